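# Shipped default simulation scenario: 1 Mb synthetic chromosome, viewpoint
# at its centre, 2 conditions x 2 replicates, one fold-5 interaction domain
# spanning 100 kb starting 350 kb downstream of the viewpoint midpoint.
chrom=chrS
seq_length=1000000
base_prob_a=0.425
base_prob_c=0.075
base_prob_g=0.075
base_prob_t=0.425
motif=GATC
viewpoint_name=VP
viewpoint_pos=500000
roi_radius=500000
conditions=neuron,esc
n_replicates=2
amplitude=300
half_distance=4000
exponent=1.3
dispersion=5
depth_min=0.5
depth_max=2
domain_offset=350000
domain_width=100000
domain_fold=5
domain_condition=neuron
flank=none
flank_scale=1
flank_condition=neuron
fine_bin=1000
rebin_factor=10
exclusion_radius=50000
n_pairs=50
n_perm_meso=1000
n_perm_asym=10000
seed=20260929
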