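input_size: 299
n_classes: 6
dropout: 0.2
stem_conv: [32, 32, 64]
stem_erf: [80, 192, 256]
n_blocks_a: 5
a_br1: 32
a_br2: [32, 32]
a_erf: [32, 48, 64]
ra_conv: 384
ra_erf: [192, 224, 256]
n_blocks_b: 10
b_br1: 176
b_br2: [144, 148, 184]
rb_br1: [256, 384]
rb_br2: [256, 256]
rb_erf: [256, 256, 256]
gam_rate: 16
gam_spatial_kernel: 7
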