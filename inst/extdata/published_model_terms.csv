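family,model,descriptor,contribution
QSAR,1,nCt,0.0679
QSAR,1,nCconj,0.0631
QSAR,1,nRCO,-0.5006
QSAR,1,nROR,-0.34331
QSAR,2,nCconj,0.04241
QSAR,2,nR=Cp,0.0803
QSAR,2,nRCO,-0.5641
QSAR,3,nCconj,0.052
QSAR,3,nRCO,-0.491
QSAR,3,nROR,-0.2618
QSAR,3,nArOH,0.1229
QSAR,4,nCconj,0.0444
QSAR,4,nRCO,-0.48
QSAR,4,nROR,-0.2579
QSAR,4,nArOH,0.1518
QSAR,4,nOH,0.0187
QSAR,5,nCconj,0.3304
QSAR,5,nRCO,-0.7285
QSAR,5,nROR,-0.503
QSAR,5,nArOH,0.6552
QSAR,6,nCconj,0.3606
QSAR,6,nRCO,-0.6265
QSAR,6,nROR,-0.5205
QSAR,6,nArOH,0.6582
QPAR,1,J,-2.3271
QPAR,1,MlogP,0.3632
QPAR,1,TIE,0.0843
QPAR,1,AMR,0.0441
QPAR,2,J,-1.6812
QPAR,2,MlogP,0.3222
QPAR,2,TIE,0.0929
QPAR,2,BAC,-0.0535
QPAR,3,TIE,0.16824
QPAR,3,Qtot,0.4735
QPAR,3,Hy,-0.7359
QPAR,3,eta,0.3068
QPAR,4,TIE,0.1684
QPAR,4,Qtot,0.5324
QPAR,4,Hy,-0.4735
QPAR,4,dipole,0.0927
QPAR,5,J,-0.0638
QPAR,5,MlogP,1.5415
QPAR,5,TIE,0.2377
QPAR,5,dipole,0.5698
QPAR,5,e_homo,0.2377
QPAR,6,MlogP,1.1347
QPAR,6,TIE,0.0467
QPAR,6,dipole,0.6654
QPAR,6,e_homo,0.2486
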