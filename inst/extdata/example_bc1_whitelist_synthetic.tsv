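CAATGAATAC	bc1_001
CGAGTACTCC	bc1_002
CTCCTAAGGA	bc1_003
CATTTTTTGC	bc1_004
TTGGATCTTG	bc1_005
TAATTGACAA	bc1_006
ACCAGAACTA	bc1_007
GATGACCAGT	bc1_008
ATCGAAGGCA	bc1_009
AAGATGTACT	bc1_010
TCATATTCGC	bc1_011
GCGTACATAC	bc1_012
CTGGATGTGA	bc1_013
TGGGATTGCC	bc1_014
AGCGAAGCTC	bc1_015
GCCAGCCGGA	bc1_016
CCACGAACAT	bc1_017
ACAGTATTCT	bc1_018
GACACCACAG	bc1_019
AACAATGTTC	bc1_020
AAGGAGCTTA	bc1_021
TGTATATCTT	bc1_022
GTGAAACAAT	bc1_023
CTGTAACACT	bc1_024
CACGGATAAT	bc1_025
CGGTATAGAT	bc1_026
CAAGAAAAGT	bc1_027
CTTAGCGGGA	bc1_028
CCCGTCATAT	bc1_029
GTCCGGACTC	bc1_030
TAGGCTCAGC	bc1_031
TGGGAGCGCG	bc1_032
TTAGTGTCGT	bc1_033
GATGTGGCTA	bc1_034
GGTTTCTAAT	bc1_035
AGCGCAAGCG	bc1_036
GACGTGCCGC	bc1_037
ACTCTGACAA	bc1_038
CCACGTTGAT	bc1_039
TGTTTGGATC	bc1_040
CATTGAAATC	bc1_041
GTGAAGTTCC	bc1_042
TCTGAATGGG	bc1_043
TCACGTCGGC	bc1_044
GATTTGTGGG	bc1_045
CTCTATGCCT	bc1_046
CCTTCGAATT	bc1_047
TCTAACTGCA	bc1_048
CAAGTGCCTG	bc1_049
GTATAATGGA	bc1_050
TCCAGCAGAC	bc1_051
CATTGAGTGG	bc1_052
CGACCGGCAA	bc1_053
TCACATTTTG	bc1_054
TTTGCAGTTA	bc1_055
CGCCTGAGCG	bc1_056
AAGGGTATCT	bc1_057
CGCACAAGAA	bc1_058
TGTCGGGAGG	bc1_059
TGCAGCACAG	bc1_060
AGCGCGAAGT	bc1_061
TACAGTATCG	bc1_062
TCGGACGCGT	bc1_063
CAGCTTAACA	bc1_064
GCTGCGCACC	bc1_065
CAAGAACTTA	bc1_066
AAGTAGGACG	bc1_067
AGGTGAACAC	bc1_068
TAATGACCCA	bc1_069
GACGTCTATT	bc1_070
TCATTGTTGC	bc1_071
CTGGCGCAGA	bc1_072
CGCTTGTGAC	bc1_073
CAATCCATCC	bc1_074
AAGCACTGAT	bc1_075
ATCAGTCAAG	bc1_076
GCTGAGCAAG	bc1_077
GGGTTGTCCC	bc1_078
GGGCAAAAAC	bc1_079
GAGATTACCC	bc1_080
GAAACGTCTA	bc1_081
GGCGATCCAC	bc1_082
TGCTACGTTC	bc1_083
TTACAGCCCG	bc1_084
CAACGCGCTT	bc1_085
CCGAGCCACT	bc1_086
CGCACGATAG	bc1_087
TTAAGCCCAT	bc1_088
GATTGTGGTC	bc1_089
GTCATCCAAT	bc1_090
GACTTTAGGA	bc1_091
TGTTCGTGAC	bc1_092
TGGTCGAGTG	bc1_093
GATATTCGCA	bc1_094
GTGGGGGGAC	bc1_095
CGTGCACATC	bc1_096
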