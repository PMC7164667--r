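spheroid,n_particles,lower_bound,upper_bound,diameter_um
1,11594,9312,13172,289
2,11990,9569,13536,291
3,10357,7718,10917,271
4,6506,5140,7271,237
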