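# Feature registry presets. Each preset lists the per-beat series that are
# aggregated (by the statistics listed under `stats`, in that order) and the
# window-scalar features appended after them. Column names are
# <series>_<stat> followed by the scalars.
#
# core:  4 stats x (14 morphology series + heart_rate) = 60, plus 4
#        zero-crossing rates and the PPG Shannon entropy -> 65 features.
# full:  core + pulse-transit-time statistics (ptt_f, ptt_p) and the
#        derivative entropies -> 75 features.
presets:
  core:
    beat_series:
      - sys_amp
      - dia_amp
      - sys_area
      - dia_area
      - ipa
      - sys_time
      - dia_time
      - pulse_interval
      - stiffness_index
      - ppi
      - pulse_rate
      - fwhm
      - sa_dt_ratio
      - aug_index
      - heart_rate
    stats: [mean, sd, skew, kurt]
    scalars:
      - zcr_ppg
      - zcr_ppg_d1
      - zcr_ppg_d2
      - zcr_ecg
      - entropy_ppg
  full:
    beat_series:
      - sys_amp
      - dia_amp
      - sys_area
      - dia_area
      - ipa
      - sys_time
      - dia_time
      - pulse_interval
      - stiffness_index
      - ppi
      - pulse_rate
      - fwhm
      - sa_dt_ratio
      - aug_index
      - heart_rate
      - ptt_f
      - ptt_p
    stats: [mean, sd, skew, kurt]
    scalars:
      - zcr_ppg
      - zcr_ppg_d1
      - zcr_ppg_d2
      - zcr_ecg
      - entropy_ppg
      - entropy_ppg_d1
      - entropy_ppg_d2
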