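wavelength_nm,uv,sws,mws,lws
300,0.088922,8e-06,0,0
305,0.135335,1.9e-05,0,0
310,0.197899,4e-05,0,0
315,0.278037,8.4e-05,0,0
320,0.375311,0.00017,0,0
325,0.486752,0.000335,0,0
330,0.606531,0.000644,0,0
335,0.726149,0.001204,0,0
340,0.83527,0.002187,0,0
345,0.923116,0.003866,1e-06,0
350,0.980199,0.006645,2e-06,0
355,1,0.011109,4e-06,0
360,0.980199,0.018063,8e-06,0
365,0.923116,0.028566,1.5e-05,0
370,0.83527,0.043937,2.9e-05,0
375,0.726149,0.065729,5.5e-05,0
380,0.606531,0.095634,0.000103,0
385,0.486752,0.135335,0.000188,0
390,0.375311,0.18627,0.000335,1e-06
395,0.278037,0.249352,0.000588,1e-06
400,0.197899,0.324652,0.00101,2e-06
405,0.135335,0.411112,0.001699,4e-06
410,0.088922,0.506336,0.002802,7e-06
415,0.056135,0.606531,0.004526,1.3e-05
420,0.034047,0.706648,0.007163,2.3e-05
425,0.019841,0.800737,0.011109,4e-05
430,0.011109,0.882497,0.01688,7e-05
435,0.005976,0.945959,0.02513,0.00012
440,0.003089,0.986207,0.036658,0.000202
445,0.001534,1,0.052393,0.000335
450,0.000732,0.986207,0.07337,0.000549
455,0.000335,0.945959,0.100669,0.000884
460,0.000148,0.882497,0.135335,0.001401
465,6.3e-05,0.800737,0.178264,0.002187
470,2.5e-05,0.706648,0.230066,0.003362
475,1e-05,0.606531,0.290924,0.005086
480,4e-06,0.506336,0.360448,0.007576
485,1e-06,0.411112,0.437565,0.011109
490,0,0.324652,0.52045,0.016038
495,0,0.249352,0.606531,0.022794
500,0,0.18627,0.692569,0.031895
505,0,0.135335,0.774837,0.043937
510,0,0.095634,0.849366,0.059587
515,0,0.065729,0.912254,0.07956
520,0,0.043937,0.960005,0.104579
525,0,0.028566,0.989848,0.135335
530,0,0.018063,1,0.172422
535,0,0.011109,0.989848,0.216265
540,0,0.006645,0.960005,0.267052
545,0,0.003866,0.912254,0.324652
550,0,0.002187,0.849366,0.388558
555,0,0.001204,0.774837,0.457833
560,0,0.000644,0.692569,0.531096
565,0,0.000335,0.606531,0.606531
570,0,0.00017,0.52045,0.681941
575,0,8.4e-05,0.437565,0.75484
580,0,4e-05,0.360448,0.822578
585,0,1.9e-05,0.290924,0.882497
590,0,8e-06,0.230066,0.932102
595,0,4e-06,0.178264,0.969233
600,0,2e-06,0.135335,0.992218
605,0,1e-06,0.100669,1
610,0,0,0.07337,0.992218
615,0,0,0.052393,0.969233
620,0,0,0.036658,0.932102
625,0,0,0.02513,0.882497
630,0,0,0.01688,0.822578
635,0,0,0.011109,0.75484
640,0,0,0.007163,0.681941
645,0,0,0.004526,0.606531
650,0,0,0.002802,0.531096
655,0,0,0.001699,0.457833
660,0,0,0.00101,0.388558
665,0,0,0.000588,0.324652
670,0,0,0.000335,0.267052
675,0,0,0.000188,0.216265
680,0,0,0.000103,0.172422
685,0,0,5.5e-05,0.135335
690,0,0,2.9e-05,0.104579
695,0,0,1.5e-05,0.07956
700,0,0,8e-06,0.059587
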