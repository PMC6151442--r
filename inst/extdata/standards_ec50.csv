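standard,name,EC5,EC10,EC20,EC30,EC40,EC50
1,epimedin A,8.11,41.00,238.09,766.50,1998.72,4816.47
2,epimedin B,7.14,19.86,60.32,126.22,231.21,402.92
3,epimedin C,0.02,0.52,18.53,199.07,1394.17,8318.58
4,icariin,0.91,3.24,12.80,31.91,67.48,134.17
5,baohuoside I,13.77,21.32,34.26,46.95,60.79,77.06
6,icartin,1.90,4.73,12.73,24.56,42.09,69.02
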