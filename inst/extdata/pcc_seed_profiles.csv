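group,region,correlation
cutoff2,l-CingGyP,0.91
cutoff2,r-PreCC,0.82
cutoff2,l-CunC,0.79
cutoff2,r-CingGyAnt,0.79
cutoff2,l-PreCC,0.78
cutoff2,r-CunC,0.76
cutoff2,l-CingGyAnt,0.65
cutoff2,r-ThTemp,0.63
cutoff2,r-FrP,0.63
cutoff24,l-CingGyP,0.94
cutoff24,r-PreCC,0.85
cutoff24,l-PreCC,0.83
cutoff24,r-CingGyAnt,0.78
cutoff24,l-CunC,0.75
cutoff24,l-CingGyAnt,0.74
cutoff24,r-CunC,0.74
cutoff24,r-ThPreFr,0.72
cutoff24,r-ThTemp,0.72
cutoff24,l-ThPreFr,0.71
cutoff24,l-LingGy,0.7
cutoff24,r-SupFrGy,0.69
cutoff24,l-ThPostPar,0.69
cutoff24,r-LingGy,0.69
cutoff24,r-FrP,0.68
cutoff24,l-IntCalC,0.68
cutoff24,l-ThTemp,0.67
cutoff24,r-IntCalC,0.67
cutoff24,l-LatOccCS,0.66
cutoff24,r-PreCentGy,0.66
cutoff24,r-MiFrGy,0.66
cutoff24,l-CerVI,0.66
cutoff24,l-CerCrI,0.66
cutoff24,r-LatOccCS,0.66
cutoff24,l-ThOcc,0.65
cutoff24,l-LatOccCInf,0.65
cutoff24,l-Hyp,0.65
cutoff24,r-ParCingGy,0.65
cutoff24,r-ThPostPar,0.64
cutoff24,r-SupTempGyA,0.64
cutoff24,r-CerVI,0.64
cutoff24,r-SupCalcC,0.64
cutoff24,r-Hyp,0.64
cutoff24,r-PlaT,0.69
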