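# Homogeneous-array (model A) levitation chamber
[chamber]
lx = 10 mm
ly = 10 mm
height = 1.1 mm
fluid = water
fluid_density = 1000 kg/m3
fluid_sound_speed = 1480 m/s
top_impedance = 13 MPa.s/m
side_impedance = 17 MPa.s/m

[transducer]
units = model_A
unit_size = 2 mm
pitch = 2.4 mm
epoxy = 0.6 nm/V

[drive]
voltage = 60 V
frequency = 660 kHz

[particle]
radius = 75 um
density = 1099 kg/m3
compressibility = 4.0e-10 1/Pa
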