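# Example plate-layout configuration for phenowell::read_plate_layout().
# 'format' picks one of the built-in layouts (6-well, 12-well, 24-well);
# the remaining keys override the default geometry (all in millimetres).
format: 24-well
well_radius: 7.8
pitch: 19.30
mark_offset: 6
key_shift: 22
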