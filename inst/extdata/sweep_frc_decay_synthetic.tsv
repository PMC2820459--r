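# Synthetic FRC decay table (see sweep_model.yaml for provenance).
distance	frc
6250	0.00704
18750	0.01877
31250	0.034
43750	0.04969
56250	0.0578
68750	0.06668
81250	0.07902
93750	0.09598
106250	0.10244
118750	0.11037
131250	0.11234
143750	0.13044
156250	0.14155
168750	0.14353
181250	0.16149
193750	0.17077
206250	0.18031
218750	0.17252
231250	0.17463
243750	0.17998
256250	0.18951
268750	0.20873
281250	0.20255
293750	0.2043
306250	0.20686
318750	0.21838
331250	0.22082
343750	0.22317
356250	0.22284
368750	0.22666
381250	0.24089
393750	0.23491
406250	0.23799
418750	0.2402
431250	0.24568
443750	0.24345
456250	0.2372
468750	0.24042
481250	0.23931
493750	0.2529
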