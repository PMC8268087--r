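# Demo run: small synthetic cohort (annulus fibrosus only) plus phantom
# orientation analysis. Paths and seed are usually supplied on the command
# line; all keys mirror pipeline_config().
seed: 1
simulate: true
cohort:
  - group: control
    structure: AF
    level: C5-C6
    stage: TS24
    mean_E_ins_kPa: 24
    mean_f: 0.74
    sd_E_ins_between_kPa: 3.5
    sd_E_ins_within_kPa: 3.5
    sd_f_between: 0.03
    sd_f_within: 0.03
    tau1_s: 2
    n_specimens: 3
    n_indents: 6
  - group: mdg
    structure: AF
    level: C5-C6
    stage: TS24
    mean_E_ins_kPa: 37
    mean_f: 0.67
    sd_E_ins_between_kPa: 15
    sd_E_ins_within_kPa: 15
    sd_f_between: 0.054
    sd_f_within: 0.054
    tau1_s: 2
    n_specimens: 3
    n_indents: 6
noise_sd_uN: 0.001
section_thickness_um: 25
orientation: true
n_images_per_group: 2
image_size_px: 128
n_fibers: 40
window_sigma_px: 10
log_level: INFO
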