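serial,true,R,G,B,predicted
1,500,53.35,177.52,171.15,500.0475
2,450,58.99,179.44,167.47,457.5366
3,400,66.21,181.74,164.93,404.6016
4,350,74.55,184.28,162.4,358.8658
5,300,82.64,186.66,157.8,305.5325
6,250,95.33,190.24,157.33,256.276
7,200,108.2,193.72,154.78,203.2454
8,150,123.08,197.62,152.21,145.2632
9,100,142.94,203.39,149.06,99.3458
10,75,150.2,205.43,147.48,75.0586
11,50,161.97,210.17,144.37,48.9074
12,30,171.31,213.58,145.07,29.0233
13,15,196.36,228.5,127.35,15.0114
14,0,227.63,238.84,122.85,0.3451
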