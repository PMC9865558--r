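wavelength_nm,R,G,B
400,2.6e-05,0.001312,0.094832
405,4.2e-05,0.002017,0.125571
410,6.7e-05,0.003052,0.162262
415,0.000107,0.004545,0.204619
420,0.000168,0.006665,0.251808
425,0.00026,0.009623,0.302407
430,0.000398,0.013677,0.354414
435,0.000602,0.019137,0.405347
440,0.000899,0.026362,0.452418
445,0.001326,0.035752,0.492776
450,0.001933,0.047736,0.52379
455,0.002782,0.062747,0.543327
460,0.003956,0.081201,0.55
465,0.005555,0.103453,0.543327
470,0.007704,0.129759,0.52379
475,0.010555,0.160231,0.492776
480,0.014283,0.194792,0.452418
485,0.01909,0.233135,0.405347
490,0.025203,0.2747,0.354414
495,0.032864,0.318658,0.302407
500,0.042329,0.363919,0.251808
505,0.053851,0.409165,0.204619
510,0.067668,0.452904,0.162263
515,0.083987,0.493547,0.125571
520,0.102962,0.529498,0.094832
525,0.124677,0.559262,0.069891
530,0.149118,0.58154,0.050267
535,0.176162,0.595331,0.035281
540,0.205557,0.600001,0.024166
545,0.236914,0.595332,0.016154
550,0.269705,0.581541,0.010538
555,0.303267,0.559263,0.006709
560,0.336821,0.5295,0.004168
565,0.369498,0.493549,0.002528
570,0.400371,0.452906,0.001497
575,0.428501,0.409167,0.000866
580,0.452981,0.363922,0.00049
585,0.472984,0.318662,0.000272
590,0.487811,0.274705,0.000149
595,0.49693,0.233142,8.2e-05
600,0.500008,0.1948,4.7e-05
605,0.496933,0.160241,2.9e-05
610,0.487818,0.129771,2.1e-05
615,0.472995,0.103468,1.9e-05
620,0.452996,0.081219,2e-05
625,0.428521,0.062769,2.3e-05
630,0.400396,0.047763,2.7e-05
635,0.369529,0.035785,3.3e-05
640,0.336859,0.026402,4e-05
645,0.303314,0.019186,4.9e-05
650,0.269764,0.013737,6e-05
655,0.236987,0.009696,7.3e-05
660,0.205646,0.006755,9e-05
665,0.17627,0.004655,0.000109
670,0.149251,0.003185,0.000134
675,0.124839,0.00218,0.000163
680,0.103161,0.001512,0.000199
685,0.08423,0.001084,0.000243
690,0.067964,0.000827,0.000297
695,0.054213,0.000691,0.000362
700,0.042771,0.000643,0.000442
705,0.033404,0.000661,0.00054
710,0.025861,0.00073,0.000658
715,0.019893,0.000845,0.000803
720,0.015262,0.001004,0.00098
725,0.011749,0.001208,0.001194
730,0.00916,0.001463,0.001455
735,0.007327,0.001777,0.001773
740,0.006114,0.002161,0.002158
745,0.005408,0.002627,0.002626
750,0.005125,0.003192,0.003192
755,0.005202,0.003876,0.003875
760,0.005599,0.0047,0.0047
765,0.006293,0.005691,0.005691
770,0.007277,0.006879,0.006879
775,0.008557,0.008297,0.008297
780,0.010148,0.009981,0.009981
785,0.012077,0.01197,0.01197
790,0.014372,0.014304,0.014304
795,0.017064,0.017022,0.017022
800,0.020183,0.020158,0.020158
805,0.023754,0.023738,0.023738
810,0.027786,0.027777,0.027777
815,0.032278,0.032273,0.032273
820,0.037206,0.037203,0.037203
825,0.042523,0.042521,0.042521
830,0.048159,0.048157,0.048157
835,0.054021,0.05402,0.05402
840,0.06,0.06,0.06
845,0.06598,0.06598,0.06598
850,0.071843,0.071843,0.071843
855,0.077479,0.077479,0.077479
860,0.082797,0.082797,0.082797
865,0.087727,0.087727,0.087727
870,0.092223,0.092223,0.092223
875,0.096262,0.096262,0.096262
880,0.099842,0.099842,0.099842
885,0.102978,0.102978,0.102978
890,0.105696,0.105696,0.105696
895,0.10803,0.10803,0.10803
900,0.110019,0.110019,0.110019
905,0.111703,0.111703,0.111703
910,0.113121,0.113121,0.113121
915,0.114309,0.114309,0.114309
920,0.1153,0.1153,0.1153
925,0.116125,0.116125,0.116125
930,0.116808,0.116808,0.116808
935,0.117374,0.117374,0.117374
940,0.117842,0.117842,0.117842
945,0.118227,0.118227,0.118227
950,0.118545,0.118545,0.118545
955,0.118806,0.118806,0.118806
960,0.11902,0.11902,0.11902
965,0.119197,0.119197,0.119197
970,0.119342,0.119342,0.119342
975,0.11946,0.11946,0.11946
980,0.119558,0.119558,0.119558
985,0.119638,0.119638,0.119638
990,0.119703,0.119703,0.119703
995,0.119757,0.119757,0.119757
1000,0.119801,0.119801,0.119801
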