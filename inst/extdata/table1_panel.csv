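transmitter,count_mean,count_sd,provenance
TK,12.16,0.55,published per-AL cell-body count (mean +- sd; n = 6 brains)
FMRF,58.16,17.48,published per-AL cell-body count (mean +- sd; n = 6 brains)
Mas-AT,143.58,24.38,published per-AL cell-body count (mean +- sd; n = 6 brains)
MIP,150.66,16.79,published per-AL cell-body count (mean +- sd; n = 6 brains)
AST-A,47.4,12.83,published per-AL cell-body count (mean +- sd; n = 6 brains)
GABA,170,0,approximate GABAergic LN total; sd unpublished (encoded as 0)
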