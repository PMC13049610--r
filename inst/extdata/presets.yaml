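# Built-in instrument, tissue and cell presets.
# All lengths/forces in SI units unless the key says otherwise.
# Tissue presets encode the regional Young's modulus summaries (mean +/- SD,
# kPa) that the synthetic generator reproduces; 'source' is a plain
# description of the tissue/condition each preset emulates.
instruments:
  colloidal:
    tip_shape: sphere
    tip_radius_m: 5.4e-6
    spring_constant_N_per_m: 0.2
    poisson_ratio: 0.5
    setpoint_force_N: 1.6e-8
    z_length_m: 6.0e-6
    z_step_m: 5.0e-9
    grid_n: 16
    grid_extent_m: 2.0e-5
    max_fit_depth_m: 6.0e-6
    noise_sd_force_N: 5.0e-11
    baseline_slope_sd_N_per_m: 1.0e-5
    contact_offset_min_m: 5.0e-7
    contact_offset_max_m: 1.5e-6
    source: "colloidal-probe AFM, 10.8 um polystyrene bead cantilever
      (nominal k 0.2 N/m), quantitative-imaging maps on 100 um fresh
      vibratome heart sections, 16 nN setpoint, 6 um ramp"
  nanoindenter:
    tip_shape: cono_spherical
    tip_radius_m: 1.0e-4
    spring_constant_N_per_m: 5.0e+3
    poisson_ratio: 0.5
    setpoint_force_N: 5.0e-5
    z_length_m: 1.0e-4
    z_step_m: 8.0e-8
    grid_n: 1
    grid_extent_m: 1.0e-6
    max_fit_depth_m: 3.0e-5
    noise_sd_force_N: 1.0e-7
    baseline_slope_sd_N_per_m: 1.0e-3
    contact_offset_min_m: 5.0e-6
    contact_offset_max_m: 1.5e-5
    source: "large-displacement depth-sensing indenter, rigid cono-spherical
      probe r = 100 um on whole hearts; sphere-dominated regime fitted for
      indentation depth < 30 um"
tissues:
  cortical:
    E_mean_kPa: 8.1
    E_sd_kPa: 2.9
    pixel_cv: 0.3
    source: "cortical myocardium, non-injured hearts"
  trabeculated:
    E_mean_kPa: 3.0
    E_sd_kPa: 1.3
    pixel_cv: 0.3
    source: "trabeculated myocardium, non-injured hearts"
  injury14_myocardium:
    E_mean_kPa: 2.1
    E_sd_kPa: 0.5
    pixel_cv: 0.3
    source: "injury-adjacent myocardium, 14 days post-cryoinjury"
  injury14_center:
    E_mean_kPa: 1.0
    E_sd_kPa: 0.8
    pixel_cv: 0.3
    source: "cell-rich injury centre (DAPI++), 14 days post-cryoinjury"
  injury14_dapi_neg:
    E_mean_kPa: 10.1
    E_sd_kPa: 5.6
    pixel_cv: 0.3
    source: "cell-poor fibrin band (DAPI-), 14 days post-cryoinjury"
  dmso_fibrin:
    E_mean_kPa: 9.0
    E_sd_kPa: 8.0
    pixel_cv: 0.3
    source: "fibrin band (DAPI-), 7 days post-cryoinjury, DMSO control"
  dmso_center:
    E_mean_kPa: 2.7
    E_sd_kPa: 2.6
    pixel_cv: 0.3
    source: "injury centre, 7 days post-cryoinjury, DMSO control"
  dmso_myocardium:
    E_mean_kPa: 2.1
    E_sd_kPa: 1.0
    pixel_cv: 0.3
    source: "injury-adjacent myocardium, 7 days post-cryoinjury, DMSO control"
  tp_fibrin:
    E_mean_kPa: 4.3
    E_sd_kPa: 3.0
    pixel_cv: 0.3
    source: "fibrin band (DAPI-), 7 days post-cryoinjury, tiplaxtinin-treated"
  tp_center:
    E_mean_kPa: 2.1
    E_sd_kPa: 2.0
    pixel_cv: 0.3
    source: "injury centre, 7 days post-cryoinjury, tiplaxtinin-treated"
  tp_myocardium:
    E_mean_kPa: 2.1
    E_sd_kPa: 1.0
    pixel_cv: 0.3
    source: "injury-adjacent myocardium, 7 days post-cryoinjury,
      tiplaxtinin-treated"
  global_noninjured_distal:
    E_mean_kPa: 11.2
    E_sd_kPa: 7.0
    pixel_cv: 0.3
    source: "whole-heart indentation, distal ventricle, non-injured"
  global_noninjured_proximal:
    E_mean_kPa: 7.7
    E_sd_kPa: 6.0
    pixel_cv: 0.3
    source: "whole-heart indentation, proximal ventricle, non-injured"
  global_9dpci_distal:
    E_mean_kPa: 6.7
    E_sd_kPa: 3.0
    pixel_cv: 0.3
    source: "whole-heart indentation, distal ventricle, 9 days post-cryoinjury"
  global_9dpci_proximal:
    E_mean_kPa: 4.1
    E_sd_kPa: 2.0
    pixel_cv: 0.3
    source: "whole-heart indentation, proximal ventricle, 9 days
      post-cryoinjury"
  global_14dpci_distal:
    E_mean_kPa: 7.5
    E_sd_kPa: 3.0
    pixel_cv: 0.3
    source: "whole-heart indentation, distal ventricle, 14 days
      post-cryoinjury"
  global_14dpci_proximal:
    E_mean_kPa: 6.2
    E_sd_kPa: 3.0
    pixel_cv: 0.3
    source: "whole-heart indentation, proximal ventricle, 14 days
      post-cryoinjury"
cells:
  yap_fibrin_dmso:
    p_positive: 0.345
    source: "endocardial cells adjacent to the fibrin band, nuclear-YAP
      positive, DMSO control"
  yap_fibrin_tp:
    p_positive: 0.16
    source: "endocardial cells adjacent to the fibrin band, nuclear-YAP
      positive, tiplaxtinin-treated"
  yap_periphery_dmso:
    p_positive: 0.228
    source: "endocardial cells at the injury periphery, nuclear-YAP
      positive, DMSO control"
  yap_periphery_tp:
    p_positive: 0.094
    source: "endocardial cells at the injury periphery, nuclear-YAP
      positive, tiplaxtinin-treated"
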