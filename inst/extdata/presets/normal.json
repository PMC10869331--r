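{
  "schema_version": 1,
  "name": "NORMAL",
  "description": "Healthy physiology: LV Ees 1.6 / RV Ees 1.6 mmHg/mL, HR 80 bpm, SVR 17 WU, PVR 0.8 WU. Element-level constants are calibrated defaults (see methods vignette); characteristic impedances are ~5% of the respective resistive totals. Initial volumes are the documented operating state (total stressed volume 803 mL).",
  "circuit": {
    "R_MV": 0.004,
    "R_AV": 0.005,
    "R_TV": 0.003,
    "R_PAV": 0.004,
    "R_SZ0": 0.051,
    "R_SA": 0.806,
    "R_SC": 0.143,
    "R_SV": 0.02,
    "R_PZ0": 0.0024,
    "R_PA": 0.0288,
    "R_PC": 0.012,
    "R_PV": 0.0048,
    "C_SA": 2.0,
    "C_SC": 5.0,
    "C_SV": 25,
    "C_PA": 2.0,
    "C_PC": 2.5,
    "C_PV": 3.0,
    "A_MV": 4.0,
    "A_AV": 3.0,
    "A_TV": 5.0,
    "A_PAV": 3.5,
    "HR": 80,
    "rho": 1.05
  },
  "chambers": {
    "LV": {
      "E_es": 1.6,
      "E_min": 0.05,
      "V0": 10,
      "edpvr_alpha": 0.225,
      "edpvr_beta": 0.03,
      "t_activation_onset": 0.0,
      "t_activation_duration": 0.63
    },
    "RV": {
      "E_es": 1.6,
      "E_min": 0.04,
      "V0": 40,
      "edpvr_alpha": 0.9,
      "edpvr_beta": 0.0178,
      "t_activation_onset": 0.0,
      "t_activation_duration": 0.63
    },
    "LA": {
      "E_es": 0.45,
      "E_min": 0.12,
      "V0": 5,
      "edpvr_alpha": 0.94,
      "edpvr_beta": 0.05,
      "t_activation_onset": 0.82,
      "t_activation_duration": 0.2
    },
    "RA": {
      "E_es": 0.12,
      "E_min": 0.08,
      "V0": 5,
      "edpvr_alpha": 0.78,
      "edpvr_beta": 0.05,
      "t_activation_onset": 0.82,
      "t_activation_duration": 0.2
    }
  },
  "devices": {
    "vaecmo_flow": 0,
    "impella_level": 0,
    "vvecmo_on": false,
    "Hb": 15,
    "SaO2_native": 0.98,
    "SaO2_vv": 0.98
  },
  "initial_volumes": {
    "V_LA": 45,
    "V_LV": 120,
    "V_RA": 40,
    "V_RV": 115,
    "V_SA": 180,
    "V_SC": 90,
    "V_SV": 125,
    "V_PA": 36,
    "V_PC": 25,
    "V_PV": 27
  },
  "engine": {
    "dt": 0.0002,
    "decimation": 5,
    "limiter_gain": 1.0,
    "v_floor": 1.0,
    "p_max": 500
  }
}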