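# Mechanical circulatory support devices: Impella head-capacity behaviour
# with the LV suction limiter, VA-ECMO constant trans-circuit flow, and
# VV-ECMO as an arterial-saturation modifier.

#' Device settings
#'
#' @param vaecmo_flow VA-ECMO flow in L/min (continuous drain from the
#'   systemic veins, return to the systemic arteries)
#' @param impella_level Impella rotational-speed level, integer 0 (off, "P0")
#'   to 9 ("P9")
#' @param vvecmo_on logical; when `TRUE` the arterial saturation seen by the
#'   native-lung pathway is `SaO2_vv` instead of `SaO2_native`
#' @param Hb haemoglobin concentration (g/dL)
#' @param SaO2_native,SaO2_vv arterial oxygen saturations (fractions in
#'   (0, 1]) without / with VV-ECMO
#' @return an object of class `ecp_devices`
#' @export
device_settings <- function(vaecmo_flow = 0, impella_level = 0,
                            vvecmo_on = FALSE, Hb = 10,
                            SaO2_native = 0.40, SaO2_vv = 0.80) {
  stopifnot(is.numeric(vaecmo_flow), length(vaecmo_flow) == 1,
            vaecmo_flow >= 0, is.logical(vvecmo_on), Hb > 0)
  if (!(impella_level %in% 0:9))
    stop("impella_level must be an integer in 0..9 (P0-P9)")
  for (s in c(SaO2_native, SaO2_vv))
    if (!is.numeric(s) || s <= 0 || s > 1)
      stop("SaO2 fractions must lie in (0, 1]")
  structure(list(vaecmo_flow = vaecmo_flow,
                 impella_level = as.integer(impella_level),
                 vvecmo_on = vvecmo_on, Hb = Hb,
                 SaO2_native = SaO2_native, SaO2_vv = SaO2_vv),
            class = "ecp_devices")
}

#' Default Impella head-capacity curve table
#'
#' Quadratic head-capacity ("H-Q") coefficients per rotational-speed level:
#' `dP = a - b*Q - c*Q^2` with dP in mmHg and Q in L/min. The shipped table
#' (`inst/extdata/hq_curves.csv`) follows pump affinity scaling from a P9
#' curve with a 120 mmHg shut-off head and 3.70 L/min zero-head flow
#' (Impella-CP class); substitute manufacturer data by passing your own
#' table with columns `level`, `a`, `b`, `c` covering levels 0..9.
#'
#' @param path optional CSV path overriding the shipped table
#' @return data.frame with columns level (0..9), a, b, c
#' @export
default_hq_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hq_curves.csv", package = "ecpella")
  hq <- read.csv(path)
  need <- c("level", "a", "b", "c")
  if (!all(need %in% names(hq)))
    stop("H-Q table must have columns: ", paste(need, collapse = ", "))
  hq <- hq[order(hq$level), need]
  if (!identical(as.integer(hq$level), 0:9))
    stop("H-Q table must cover levels 0..9 exactly once")
  if (any(hq$a[hq$level > 0] <= 0))
    stop("H-Q zero-flow heads must be positive for P1-P9")
  if (is.unsorted(hq$a))
    stop("H-Q zero-flow head must be non-decreasing in level")
  hq
}

.hq_matrix <- function(hq) as.matrix(hq[, c("a", "b", "c")])

#' Impella flow from the head-capacity curve
#'
#' Solves the level's quadratic `head = a - b*Q - c*Q^2` for the delivered
#' flow at a given pump head (systemic arterial pressure minus LV pressure).
#' Heads at or above the shut-off head `a` give zero flow; negative heads
#' are clamped at the curve's zero-head (maximum) capacity. Flow is
#' non-increasing in head at fixed level and non-decreasing in level at
#' fixed head.
#'
#' @param level integer 0..9 ("P0".."P9"); P0 always gives 0
#' @param head pump head SAP - LVP in mmHg, vectorized
#' @param curve an H-Q table as from [default_hq_table()]
#' @return flow in L/min
#' @export
impella_flow <- function(level, head, curve = default_hq_table()) {
  if (!(length(level) == 1 && level %in% 0:9))
    stop("unknown Impella level: must be a single integer in 0..9")
  if (level == 0) return(rep(0, length(head)))
  row <- curve[curve$level == level, ]
  eff <- pmax(ifelse(head <= 0, row$a, row$a - head), 0)
  (-row$b + sqrt(row$b^2 + 4 * row$c * eff)) / (2 * row$c)
}

#' LV suction limiter
#'
#' LV suction is defined as the left atrial pressure reaching 0 mmHg. When
#' LAP falls below 0 the Impella flow is throttled linearly:
#' `Q_effective = max(0, Q_nominal - limiter_gain * |LAP|)`. The result is
#' continuous in LAP; the suction flag is `TRUE` whenever `LAP <= 0`.
#'
#' @param LAP left atrial pressure (mmHg), vectorized
#' @param Q_nominal nominal Impella flow (L/min)
#' @param limiter_gain throttle slope in (L/min)/mmHg
#' @return list with `Q_effective` (L/min) and logical `suction`
#' @export
suction_limiter <- function(LAP, Q_nominal, limiter_gain = 1.0) {
  stopifnot(all(Q_nominal >= 0), limiter_gain >= 0)
  q <- ifelse(LAP < 0, pmax(0, Q_nominal - limiter_gain * (-LAP)), Q_nominal)
  list(Q_effective = q, suction = LAP <= 0)
}

#' VA-ECMO drain and return flows
#'
#' The VA-ECMO circuit is an ideal constant-flow pump: it removes blood from
#' the systemic veins and returns the same flow to the systemic arteries.
#'
#' @param settings an [device_settings()]
#' @return named numeric (mL/s): `drain` (from SV) and `return` (to SA)
#' @export
vaecmo_flows <- function(settings) {
  q <- settings$vaecmo_flow * 1000 / 60
  c(drain = q, `return` = q)
}

#' Effective arterial saturation of the native-lung pathway
#'
#' VV-ECMO oxygenates venous blood upstream of the lungs, raising the
#' saturation of blood ejected by the heart and the Impella; it does not
#' change the haemodynamics.
#'
#' @param settings an [device_settings()]
#' @return SaO2 fraction
#' @export
effective_sao2 <- function(settings)
  if (isTRUE(settings$vvecmo_on)) settings$SaO2_vv else settings$SaO2_native
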