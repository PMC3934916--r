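>IGHV1-S1*01
GTGACGTTTCAGTACACACCTGGTGTGGTCCAATCAACACAGACGGTTCCACGTGCTGTCTTAAAGCAGC
GCACAACGATCAGGTCTCCAACTCGAAAATTAGGTATGAGTCAAATTAGCCTCCATGGTTCGACATTGCA
TCCTAGGCGATCTTTGACTGAAGCTACCCAACACGTGGCGCGTGCTTCCTCCTTCGCATTAGATCCGTTC
GACAATGGTTACAAATCTATGGTGAACACAAGGAGTTATCGGTGCCCATATAGCACCCGGCTAACGCGAG
AAGTTTCTCGATGT
>IGHV1-S2*01
CCTCAAGTGCCTTCTGTTAAAGACAAACCGACAGAGACAAACAGTCCTCGCTGGGCGGATCCCATACTAG
ATGGACGGCTGAGATATGAGCCGAGCGAGGGTGTATCGCGGGACAATTTTTGGCTTTCTTATGACCTACG
TAGCAGTAGTGAAATGGGCGAGCGGCAGGCCATACTGGTTCTTGTCTCCGAAGTCAGCACGCTAGTGGAT
GTGGCTATCACTATTATATCCCATAATATCTCCCCAGGACTCACTAGTCACGGATGCCGTAAGTTTTTCG
AACAAACTCAGTGT
>IGHV3-S1*01
CTTACTGGATTCATCATACGCTACGAGCGAGATACGTACGTGGTGTCTACCCTTCTTCGAGGTATGACGA
CCGATCGTATCAGGAGCGCAGGTATACTGGGCCGCATTGCAACACCATGTCTGTATCTGTGGATCGGAGT
GGGGGCATTTCTGATGCGATTCATCTCGCTATTAACGTGGTGCTTTATTGCCGGAATCACGGTCGAATCC
GACCTATACTCATATAAGCAGTTACCTGCGGTCCGAGGACTCCGGGAGCCACAGCTAGATCAAATGGGGA
ATAGCAAGCATTGT
>IGHV3-S2*01
GATCCAGACGATGGTAGGACGAGCCTCCCGACTCAGAATTTTCTTGTAGTGTGTCGACCTGACACTGGTA
GTACACCACTCGGGTCAGTGCGCATTTCTCATCCAGCTGGTAAGTGTCGAAATAGTTATCACCGTGCCAA
GTGTCCCCGACCGACAAGTCATCAGGATGGCGTGATTGGCCCGAGACCGTCCGTCAAGTACCAAGCTGAC
TCACTTTGCGCGGCCTACGAGCAGACGTTCACCACTCGCGTTATCCGCCTAACAGAAGCGCAAAATGCAC
CGCCATGTGGTTGT
>IGHV3-S3*01
CTTCGAATGCGGACAAGGATAAATCATAGAGGGTCAAGATCTATCATACCTAACTGGGGTATTGATTTCC
GATTAATGGTCCGGCCAAGCTATGATTACTCAGCCCGACCTCAGAGATACTATCCCCTCGTTGACTTACA
TGGGCCAAGTACTCACCTGCCTCCCGTTCTGATTTACACGAGGGCTGCCGCCTACGTAACTGGTTTGCAG
CGTGGGAACATGGTTGCACATGCCAGACCCTCCAGACAGATTAGTAACGCCCAGTTCAATTATGAATGTT
CCATCTCTCTTTGT
>IGHV4-S1*01
TTTAAGTACGTGTGCCATTTTAGCGAGTTGTTAGGCGCGAATGGGGGCTCTAGTCCAACTCACACAGAGG
AGCCATATCGCGTTGTTTTAATCCCTTACATGAAACCAGCGACGTCCCGGGTTTTGCGCTATAAACACGT
ACGTTGCTACGTTGACAGCCACGATGAGCGCACTCTAGTTCAGCGACTCGTGAATCACGGGCCCTACTGG
AATTTTTGTAGGCGTGGTTACGGCAGGCTCCTGGTCTCGACATCCTACGGACGCCCAGAACAGCAACTAA
GACTAGCCTTATGT
>IGHV4-S2*01
TTATACCCGAGTTCACCCCGGAGGAGTGACGTTCAACGGGAAATTAGCAGGACCAGTGCCACTAACGCAC
CGGCGAGCGGTAGCCGTATGGCGTCCGGTCACAGTAAGGGAAGAGGAAGGCCTGTCCCGATGTGTAAAAG
GCTTTTCAATAGGACCCGAAGGCTAGCCCTAAGGAGGTCGGAGGGGGACAGGAATAATTCGGGTATCACG
CACAAGTACGGCGGAGGTTGTCGCCACATGCATCTCTTGGGAAACAGCTACTCGATCCGAACCAGGCCAG
ACGAAGTATCGTGT
>IGHV5-S1*01
GTATGTTGGAACCCTAACCCGTCTATCGAACCACCTAACGTGGGTTTAGTATCGCCCGCTTACCTCGGGT
GCACCGCAGTAATAGGGGATAGTACTAAATTTTGGTCATGTTGTTGGACGACTCTCACGCTTACGCGTGT
GCGACCTGGCGATCTGGCTAACAGGACTTGCATTACCCCACGTCAGTCGCCACGAGACGTTATGGAAGTT
CCGGAAGCTGAAACTTCTAGTTGCTTAGGTCCTGCTGCTGTCTTTTCGGCCAAAATTCCAGCCACTCCGG
CACCCGGGGGTTGT
>IGHD1-S1*01
CTTCACCTGATGTGG
>IGHD2-S1*01
AGCGAGGGTACTGATAGA
>IGHD3-S1*01
TATACGACAATGCACGTAGTC
>IGHD4-S1*01
TCGATACGTCATTGGTACGAACAG
>IGHJ1-S1*01
TTCGTATTCTGGGGCATTCATCGTGTGCCAATCAAAATT
>IGHJ2-S1*01
AAGCTCATGTCTTGGGGCCATGTGTGTGGCTATCCTAGCCCC
>IGHJ3-S1*01
AGAATGCAGCCCAACTGGGGCGAGGACCCTGGATTGCTCTCACTT
>IGHJ4-S1*01
CGGATCAAGCAGGATGAGTGGGGCCGGCGCAACAGTCTGACTCCAGTG
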