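# Canonical three-state synthetic DEER scenario: one spin-label pair under
# three biochemical conditions sharing the intermolecular background.
group_id: "542/661"
seed: 101
t_max_us: 3.0
n_points: 250
snr: 30
shared_background: true
conditions:
  apo:
    depth: 0.30
    background_rate: 0.08
    components:
      - {center_nm: 4.5, width_nm: 0.35, weight: 1.0}
  amp_pnp:
    depth: 0.35
    background_rate: 0.08
    components:
      - {center_nm: 3.0, width_nm: 0.30, weight: 1.0}
  adp_vi:
    depth: 0.28
    background_rate: 0.08
    components:
      - {center_nm: 3.0, width_nm: 0.30, weight: 0.65}
      - {center_nm: 4.5, width_nm: 0.35, weight: 0.35}
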