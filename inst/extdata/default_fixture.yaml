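# Shared simulation fixture: desk-scale analogue of a multi-batch retinal
# tissue atlas. Ages (dpc) are supplied by the caller for fetal simulations.
n_genes: 2000
cell_types: [RGC, amacrine, bipolar, horizontal, muller_glia, rod, cone]
n_markers: 50
marker_effect: 2
n_batches: 8
batch_sd: 0.15
cells_per_batch: 1400
libsize_sdlog: 0.3
dispersion: 0.3
n_ramp_genes: 50
ramp_slope: 2
seed: 1
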