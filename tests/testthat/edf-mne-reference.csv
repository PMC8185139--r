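Ch01,Ch02
-0.3474513214,-0.01323323857
-0.1575437345,-1.401432017
0.3304731664,-0.9032658494
0.7710439797,-1.22972785
0.9369204314,-0.8209150744
2.547622678,-0.472324804
3.137186529,0.1284997279
2.412432137,0.5275088402
1.18967868,0.2122510263
-1.085145556,-0.1258353187
-2.262178238,1.508295366
-1.658195705,2.745237619
-0.5988539673,2.236287422
0.7611850524,2.034331949
1.263374161,-0.1430617563
3.314400748,0.8448674391
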