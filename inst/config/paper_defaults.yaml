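# Default parameters of the lamina quantification pipeline.
# Spacings/sigmas in nm unless suffixed _vox.
optics:
  lambda_nm: 509        # GFP emission
  na: 1.32
  magnification: 63
  sigma_r_nm: 62        # lateral Gaussian PSF width
  sigma_z_nm: 190       # axial Gaussian PSF width
segmentation:
  sigma_l_nm: 60        # lateral smoothing, ~1/6 of lateral PSF extent
  sigma_a_nm: 900       # axial smoothing, 15 voxels at 60 nm pitch
  alpha: 0.9
  ic_fraction: 0.3333333333333333   # transition intensity = max(i_blur)/3
  closing_radius_vox: 2.7           # digital sphere, 81 voxels
measurement:
  clip_k: 4
  sigma_g_vox: 3        # Gaussian derivative scale (~180 nm)
  sigma_w_vox: 7        # structure-tensor averaging scale (~420 nm)
  gradient_floor: 1.0e-2
classification:
  model: linear
  features: [K_naaGc, i_average]
seed: 1
log_level: info
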