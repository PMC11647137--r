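alias	symbol
PDL1	CD274
PD-L1	CD274
B7-H1	CD274
B7H1	CD274
CD274	CD274
PDL2	PDCD1LG2
PD-L2	PDCD1LG2
B7-DC	PDCD1LG2
CD273	PDCD1LG2
PDCD1LG2	PDCD1LG2
PD1	PDCD1
PD-1	PDCD1
CD279	PDCD1
PDCD1	PDCD1
CTLA-4	CTLA4
CD152	CTLA4
CTLA4	CTLA4
CD223	LAG3
LAG-3	LAG3
LAG3	LAG3
TIM3	HAVCR2
TIM-3	HAVCR2
CD366	HAVCR2
HAVCR2	HAVCR2
VSTM3	TIGIT
WUCAM	TIGIT
TIGIT	TIGIT
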