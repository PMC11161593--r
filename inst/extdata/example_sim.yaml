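# Example simulation configuration for `minfluxvpp simulate`.
# Units are explicit in the key names; angles are degrees.
na: 1.35
refractive_index: 1.406
wavelength_nm: 635
aperture_diameter_mm: 6.5
beam_diameter_mm: 7.0
beam_profile: flat
pupil_n: 96
dims: 1
L_nm: 50
background_b: 0.005
emitter_nm: [5, 0, 0]
brightness_per_us: 100
dwell_us: 1
cycles: 60
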