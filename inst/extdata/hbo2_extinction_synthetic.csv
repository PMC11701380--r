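# synthetic modeled oxyhemoglobin molar extinction spectrum (decadic, M^-1 cm^-1, tetramer basis)
# built from a smooth log-space spline through canonical alpha/beta band anchor values;
# NOT a transcription of any published compilation -- intended for simulation and testing
wavelength_nm,epsilon_M_cm
450,62816
452,60825.2
454,58443.7
456,55779.6
458,52934.5
460,50000
462,47052.3
464,44142.9
466,41311.3
468,38589
470,36000
472,33573.6
474,31374.3
476,29458.3
478,27866.1
480,26629
482,25749
484,25128.8
486,24660.4
488,24247.3
490,23800
492,23257.7
494,22651.9
496,22032.9
498,21446
500,20932
502,20526.1
504,20254
506,20140.1
508,20211.4
510,20500
512,21027.6
514,21749
516,22597.3
518,23496
520,24356
522,25123.5
524,25938
526,27010.5
528,28590.5
530,31000
532,34561
534,39142.6
536,44318.4
538,49365.7
540,53236
542,55015.2
544,55196.4
546,54750.7
548,53876.6
550,52000
552,48759
554,44432.3
556,39495.4
558,35093.6
560,32613
562,32737.6
564,34679.5
566,37386.4
568,40396.2
570,44000
572,48351.7
574,52413.5
576,54480
578,53300.7
580,50104
582,46214.4
584,41143.2
586,34479.3
588,27010.3
590,20000
592,14168.3
594,9728.2
596,6563.8
598,4470.8
600,3200
602,2481.8
604,2066.5
606,1811.9
608,1641.1
610,1506
612,1378.4
614,1256.1
616,1141.6
618,1036.6
620,942
622,858
624,783.8
626,718.3
628,660.7
630,610
632,565.6
634,527
636,493.8
638,465.6
640,442
642,422.6
644,406.4
646,392.5
648,379.9
650,368
652,356.3
654,345.1
656,334.8
658,326
660,319
662,314
664,310.6
666,308.2
668,306.5
670,305
672,303.3
674,301.4
676,299.5
678,297.7
680,296
682,294.6
684,293.5
686,292.5
688,291.7
690,291
692,290.4
694,289.7
696,289.2
698,288.6
700,288
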