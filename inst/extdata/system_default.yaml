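# LED-array Fourier ptychographic microscope: 15x15 LED matrix (532 nm)
# 90 mm below the sample, 4 mm LED pitch, 2x / 0.1 NA objective, camera
# pixel 3.45 um; 32x32 captures reconstructed on a 128x128 grid.
wavelength_um: 0.532
led_rows: 15
led_cols: 15
led_pitch_mm: 4.0
led_distance_mm: 90.0
na_obj: 0.1
magnification: 2.0
camera_pixel_um: 3.45
lowres_size: 32
upsample_factor: 4
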