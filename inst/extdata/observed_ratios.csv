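source,target,percent,provenance
TK,GABA,84.6,published percentage of TK cells that are GABA-positive
FMRF,GABA,92.8,published percentage of FMRF cells that are GABA-positive
Mas-AT,GABA,97.2,published percentage of Mas-AT cells that are GABA-positive
MIP,GABA,97.5,published percentage of MIP cells that are GABA-positive
AST-A,GABA,96.7,published percentage of AST-A cells that are GABA-positive
TK,MIP,100,observed: every TK cell is also MIP-positive
TK,FMRF,0,observed: no TK cell is FMRF-positive
TK,Mas-AT,0,observed: no TK cell is Mas-AT-positive
MIP,Mas-AT,42,observed percentage of MIP cells that are Mas-AT-positive
Mas-AT,FMRF,22,observed percentage of Mas-AT cells that are FMRF-positive
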