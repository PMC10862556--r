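sample_id,start_date,end_date,pm10,pm25,La,La_unc,Ce,Ce_unc,V,V_unc,Ni,Ni_unc
S1,2018-08-10,2018-08-11,44.7,12.2,1.904,0.1523,2.8418,0.2273,6.8,0.476,4.11,0.2877
S2,2018-08-11,2018-08-12,58.1,19.8,1.475,0.118,2.7315,0.2185,5.9,0.413,3.106,0.2174
S3,2018-08-12,2018-08-13,115.7,37.9,2.146,0.1717,4.1269,0.3302,7.4,0.518,2.26,0.1582
S4,2018-08-13,2018-08-14,104.7,30.7,2.212,0.177,4.3373,0.347,7.9,0.553,2.48,0.1736
S5,2018-08-14,2018-08-15,84.4,22.2,1.716,0.1373,3.1778,0.2542,6.6,0.462,2.51,0.1757
S6,2018-08-15,2018-08-16,64.6,13.7,1.144,0.0915,2.2,0.176,5.2,0.364,3.664,0.2565
S7,2018-08-16,2018-08-17,74.4,13.9,1.22,0.0976,2.3462,0.1877,6.1,0.427,4.244,0.2971
S8,2018-08-17,2018-08-18,55.2,11.3,1.034,0.0827,1.7828,0.1426,4.7,0.329,3.408,0.2386
S9,2018-08-18,2018-08-19,45.1,9.3,0.77,0.0616,1.4,0.112,5.5,0.385,4.041,0.2829
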