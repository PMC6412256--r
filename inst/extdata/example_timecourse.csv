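time_h,Lref,aref,bref,L,a,b,OD
0.0,57.18,2.81,12.78,28.25,14.18,28.82,0.00
0.5,54.04,4.39,14.09,26.83,14.46,27.55,0.01
1.0,53.00,3.71,15.33,27.37,14.15,26.75,0.02
1.5,54.35,5.14,16.27,28.52,15.30,29.13,0.03
2.0,52.92,4.49,15.90,25.93,14.44,28.42,0.04
2.5,53.38,3.71,16.07,24.81,14.90,28.06,0.05
3.0,55.08,2.49,15.50,27.21,13.60,28.92,0.06
3.5,54.51,3.63,15.52,26.50,14.37,27.56,0.08
4.0,56.08,2.61,15.78,28.97,13.12,28.35,0.13
4.5,56.96,3.47,14.76,28.14,13.28,28.61,0.15
5.0,56.49,3.19,15.48,29.88,12.16,28.90,0.89
5.5,55.86,1.71,13.02,28.98,10.47,29.39,0.40
6.0,58.23,1.38,15.12,32.38,9.00,30.09,0.59
6.5,57.56,1.97,16.99,32.73,10.50,32.23,0.64
7.0,56.13,2.36,16.32,34.49,9.28,33.16,1.10
7.5,56.23,0.24,13.41,35.22,6.19,32.16,1.88
8.0,58.41,0.77,17.27,38.79,7.18,35.62,2.83
8.5,56.47,2.21,16.30,38.83,6.00,33.98,4.09
9.0,56.32,1.74,15.46,40.24,5.50,32.35,5.66
9.5,58.49,1.04,16.27,44.93,5.16,35.66,7.18
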