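# Example subject/condition configuration (average study participant).
# Lengths in metres, mass in kg, forces in N, angles in degrees.
anthropometry:
  L_ac_ecl_m: 0.358        # acromion -> lateral epicondyle
  L_ecm_psu_m: 0.27        # medial epicondyle -> ulnar styloid
  L_ecm_palm_m: 0.30       # medial epicondyle -> palm grip point
  body_mass_kg: 78.7
  sex: male
  F_hand_max_flex_N: 202.6
  F_hand_max_ext_N: 167.0
condition:
  alpha_deg: 0             # 0 = lower posture, 180 = upper posture
  m_add_kg: 2
  target_freq_hz: 0.25
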