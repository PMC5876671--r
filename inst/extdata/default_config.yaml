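# Default end-to-end configuration. Every paper-silent tunable of the
# workflow lives here; load with read_pipeline_config().
n_per_class: 30          # modelling samples per quality class (120 total)
n_per_class_external: 20 # external-validation samples per class (80 total)
gain: 3000               # white-frame counts per unit reflectance
trim: [450, 850]         # spectral window kept for modelling, nm
roi_size: 50             # ROI side length, pixels
sg_window: 11            # Savitzky-Golay window, bands (odd)
sg_polyorder: 2
prep_mode: both          # baseline correction then detrend
cal_frac: 0.6            # stratified calibration fraction
max_latent: 10           # leave-one-out latent-variable cap
n_pc: 7                  # principal components retained
select_pc: 3             # component whose loading extrema give the bands
max_pixels: 50000        # pooled-pixel cap for the image PCA
segment_image: band      # "band" (single waveband) or "pc" (score image)
segment_band: 725        # nm
glcm_levels: 64
glcm_distance: 1
gamma_grid: [1, 10, 100, 1000, 10000]
sigma2_grid: [0.1, 1, 10, 100]
cv_folds: 5
seed: 42
scene:
  height: 96
  width: 96
  fruit_center: [48.5, 48.5]
  fruit_radius: 38
  damage_radius: 9
  damage_roughness: 1.5
  noise_sd_inside: 0.010   # reflectance sd, 450-850 nm
  noise_sd_outside: 0.030  # reflectance sd outside the window (tripled)
  texture_sd: 0.010        # broadband pericarp texture sd (doubled in bruise)
  texture_corr_length: 2
  background_reflectance: 0.05
  shading: 0.04            # radial curvature falloff at the fruit rim
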