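culture,cell_line,drug,AOC_mean,AOC_sd
2D,wild_type,lorlatinib,0.44,0.04
2D,wild_type,repotrectinib,0.34,0.04
2D,wild_type,entrectinib,0.37,0.06
2D,wild_type,ceritinib,0.31,0.06
2D,wild_type,crizotinib,0.43,0.06
2D,G2032R,lorlatinib,0.44,0.02
2D,G2032R,repotrectinib,0.29,0.04
2D,G2032R,entrectinib,0.15,0.04
2D,G2032R,ceritinib,0.15,0.01
2D,G2032R,crizotinib,0.15,0.01
2D,L2026M,lorlatinib,0.38,0.04
2D,L2026M,repotrectinib,0.37,0.03
2D,L2026M,entrectinib,0.35,0.02
2D,L2026M,ceritinib,0.31,0.02
2D,L2026M,crizotinib,0.31,0.02
2D,S1986Y,lorlatinib,0.42,0.02
2D,S1986Y,repotrectinib,0.34,0.06
2D,S1986Y,entrectinib,0.33,0.07
2D,S1986Y,ceritinib,0.26,0.03
2D,S1986Y,crizotinib,0.26,0.03
3D,wild_type,lorlatinib,0.63,0.04
3D,wild_type,repotrectinib,0.56,0.04
3D,wild_type,entrectinib,0.52,0.01
3D,wild_type,ceritinib,0.51,0.01
3D,wild_type,crizotinib,0.45,0.01
3D,G2032R,lorlatinib,0.11,0.1
3D,G2032R,repotrectinib,0.08,0.09
3D,G2032R,entrectinib,0.26,0.06
3D,G2032R,ceritinib,0.18,0.003
3D,G2032R,crizotinib,0.24,0.06
3D,L2026M,lorlatinib,0.45,0.04
3D,L2026M,repotrectinib,0.25,0.03
3D,L2026M,entrectinib,0.26,0.02
3D,L2026M,ceritinib,0.43,0.003
3D,L2026M,crizotinib,0.54,0.03
3D,S1986Y,lorlatinib,0.56,0.03
3D,S1986Y,repotrectinib,0.55,0.04
3D,S1986Y,entrectinib,0.51,0.01
3D,S1986Y,ceritinib,0.51,0.02
3D,S1986Y,crizotinib,0.44,0.02
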