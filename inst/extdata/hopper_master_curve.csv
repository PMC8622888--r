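m_squared,dm2_dtau
0.05,-0.06449359
0.06931818,-0.092106432
0.08863636,-0.12060982
0.10795455,-0.14988668
0.12727273,-0.17986188
0.14659091,-0.21048282
0.16590909,-0.24171037
0.18522727,-0.27351407
0.20454545,-0.30586935
0.22386364,-0.33875586
0.24318182,-0.3721563
0.2625,-0.40605574
0.28181818,-0.44044103
0.30113636,-0.47530049
0.32045455,-0.51062359
0.33977273,-0.54640074
0.35909091,-0.58262316
0.37840909,-0.61928274
0.39772727,-0.65637195
0.41704545,-0.69388373
0.43636364,-0.73181148
0.45568182,-0.77014896
0.475,-0.80889027
0.49431818,-0.8480298
0.51363636,-0.88756223
0.53295455,-0.92748246
0.55227273,-0.96778563
0.57159091,-1.0084671
0.59090909,-1.0495223
0.61022727,-1.0909469
0.62954545,-1.1327369
0.64886364,-1.1748881
0.66818182,-1.2173968
0.6875,-1.2602591
0.70681818,-1.3034714
0.72613636,-1.3470303
0.74545455,-1.3909322
0.76477273,-1.4351739
0.78409091,-1.4797521
0.80340909,-1.5246638
0.82272727,-1.5699057
0.84204545,-1.6154751
0.86136364,-1.6613689
0.88068182,-1.7075844
0.9,-1.7541188
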