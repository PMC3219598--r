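>AluY
GGCCGGGCGCGGTGGCTCACGCCTGTAATCCCAGCACTTTGGGAGGCCGCAACTGCTGCCGGAACGATTC
ATTCACAATTCTTCCGGTGTATGGGCTGCAGGGGAACGTTAATGTAGCGTCATCCCAAACCAAAAATACA
AAAAATACATCTTATTAGGGTTGCTTGGAGAGCCTGATCGGCATGACCCTCGCACCTCAACTTAGATGCT
CCGCCCCGCAGACGTCTGCCCACCTGAGTGGGCCTCGGTGTATCAGCAACGAGGCCTCCCGATTACACTG
C
>AluYa5
GGCCGGGCGCGGTGGCTCACGCCTGTAATCCCAGCACTTTGGGAGGCCGCAACTGCTGCCGGAACGATTC
ATTCATAATTCTTCCGGTGTATGGGCTGCAGGGGAACGTTAATGTAGCATCATCCCAAACCAAAAATACA
AAAGATACATCTTATTAGGGTTGCTTGGAGAGCCTGATCGGCATGACCCTCGCACTTCAACTTAGATGCT
CCGCCCCGCAGACGTCTGCCCACCTGGGTGGGCCTCGGTGTATCAGCAACGAGGCCTCCCGATTACACTG
C
>AluYb8
GGCCGGGCGCGGTGGCTCACGCCTGTAATCCCAGCACTTTGGGAGGCCGCAACTGCTGCCGGAGCGATTC
ATTCACAATTCTTCCGGTGTATGGGCTACAGGGGAACGTTAATGTAGCGTCATCCCAAACCAAAAATACA
AAAAATACATTTTATTAGGGTTGCTTGGAGAGCTTGATCGGCATGACCCTCGCACCTCAATTTAGATGCT
CCGCCCCGCAGACGTCTACCCACCTGAGTGGGCCTCGAGTCCGGGTGCATCAGCAACGAGGCCTCCCAAT
TACACTGC
>L1
GGGGGAGGAGCCAAGATGGCTTCTTTGATCTTTATCACATCTTCTGTCTTTTGTTATGCATGATTAAACA
TCTAGAAAAACAGATAAAGGACTACGTAAGGCGAGTTATTCCATTCAGGGATATCGTAGTCTTTAGAACT
ATAGCTTGTACATTCATATTTCTAAACGTTTTACCAGATCGAATATTGCTATGATAAAAAAGCGACTGAG
AAGGATATTGTGTCCGCGGCTACCCTTATGTGTACAGACATCACACATTAAATCAATGTAGTTAATTTTG
GAGGAGATTCGAACTATAAATCCACTAAATAGCGTCTATGTCGCCAAAATTCTCCACGGTTCAGCGTCCG
ATGCTACCTGTAACCTGAAGACTGTCTCACCACTGTTAAAGAGCTAGCTCAATTGAAGGAAGAATCACAG
TGAAGGCGGGCCTTGGACCGGCTTACGAGCCCTATGGATTATTCTTGCAAATAATCACTATCGGCCCCAC
ACTATCTACTCATTTGCATTAAAAATCTCATATGTCAATGTTGTGGTTATGTTCATCTTCCTCAAGGTGT
CACTATGGGGAAACTCCGTTGACCTTATATTGGCTCGCCTTAAAACGCGTGAGGAGTATCGCGACTATGC
GCAGAGAGCCATCTTAGTATGAGCAGAAGTACAACCAGAATCATGTCTAACGTCTCACCAATTGATTGTC
AATGAAACCAATGAACTTCTAAGAGATGCGTACTAATGTGTACAGAAGAGATGACATTCTTGAAAATCAT
GTGGGAGTGTATTCGAAATAGTAACGTGGATTAAAGTACTAGCTTTGTAACTGACCGACCTCGAATCTTG
GTGGTTTGGCATGGGTTCCTAATACTTCTATGCACGACATTTTAACGGTTTATAATCACATTGGGCCTCC
TAATCTAATGAACTTGTTGGGAAGATCACCCATTTTATGTATCTGTGCCACACCGGTCATAATCCCCACC
CTCACTAAAGGACTTAAATTATGTATGGTTACCGAAAAAGATGAAACTGTCGCTACTCTTCGAAGAGAAT
CATGAAGTGCAGGGTGGGTTATAGGTAGAATTGGCGCAGGAGTTTAAGTAGTTTGAAAAAAATTTGGATG
TTTATGCCTCGCTAACATAAAACTCAGGAAATTGTTCATGCAACACATATAAGACGGCTCACGCTTATCT
CTACTATATTTCATGGGATTTCAGCTGGTCCTAAGAAACCCTTTACTTTAGTAATATATGGTTGCTCATA
TTTCAATATGTTGTACCTACGGAGCAATGTGATGCCGCACCCTGTATGTTAGATGGAAGGTTTAGCCTTT
TTGTAAAAAGCGCCACACATTTGAATAAGCTTCTATTTACAGGTGTAACGAGATTTTAAGCAGTCTAGGA
TAGTGGGTAATGCTATATAAATAACTTTATTTATTTTGGCCTTTAACATATACGGAATGCATACTTCCAA
AGCTCTACCAGTATGCAAGCTGGAATCATACAAACCCACTACTGAATGGGAAAAATCCGAGTGATCATCA
TTGCATAATATGCTAGGTTTTGTCGACATCACGTGCGCGGCATGACCACCTCGGACAGCAACATTACAAT
GGAGGGTTAAGAACGTAGCTCGTACACGGTTATGCTCGGGATAATTAAATCATCAAATGTCATGGAGGTA
TTTATGATTCTGGCGCGGTTCTGTTTCCTTGCGGACAAGAGCGTGATTAGCATTACCTCCTACAATTCTT
CTAATTAGAAAGGGCTACGTCGCACTCCATGCGCTCGATATAAACTTCCCGTTCTCGGGCGGGTTTGAAT
ACCCGATCCAGAAAACCCCACATCAAGACTAAGCGTCAGCTGCTACACTAGTTTATGCGAACGCCATACC
CCCTTCATTCGTAAAACTACTCCCCGCCACTACATAAGGTTTCCAGTATCGATTCGATCTACTTGTATTT
TCATTTTATACTGCATTAATCTATTAGTTAAAGAGGCTCCGTGCAAGTAATCTCCCCTGAGACAATTGAA
ACTCCCACACTCCTACATTAGAATAATAAACACTGCACAGTACACGATGTGTATTAATTTATGCAGGTGA
TATTTAACACCATGCTTCCGCTATTTAGGGCTAACGAGTTAAGAGACCAAAGAAATTTTAATAGTAGCAC
TTAGCCATCCTTTTACTAACGCGAAGAGTTCACACTTATTAAGAGTATATTTGATAGATTTTACCTATAT
TACTTATCAATAGTCGGTGAGTGGTTGGATCTTGGTACACGCTTTCTGTACATGATGATATGGTCTTCGA
GGCTAGTGAACATCCACAACAGCTTTATTATTCCGGGATATCCCATCTGCCGTACTATTATGTACTTCTT
TTTTGAGAACTGGGTTTAATATCATATTGACTACTTATGTAACCTCTAATAAATCTGCGCATCTAAGAAC
AGGACTATCTCTGAATTCCCTTGTTGTGCTAAGGATAGCGTTGTTGAGGAATCTGGTCCCTTCTGATACA
AGAACAGGGGTAAACACATCATCTACACACCGTTGACCCTGCTCATAAAGCCTGGCCGACAATTGAACAC
AATTCAGGTAGGTCATAAAAACTCTATTTGTTAATACACTAACTTTAATCGGGGACATATTTTGTGATAC
ATCGATCCCACCGTCGCCAAAATCACCGTGGATCAGCTAAGGCTATTTACGAGAGTCCTTTCTAGTCTTA
AATCAAGATGTCACACACCCAGGTCTCGTTATTGTATCATTCCTCCGGACCGTCAGGTCTTATGGGATAT
GTATACTAACTCCAACGCATCAGAATACATGATCGCCTAAACCTCATGCGAACCCTTACTGCCTGACAGG
GAATGTTTAACTCTAAAACCGACAAGTTGTGTTAAGCTGTTATACTCATCTATCAAGGTCAGTGTAATTT
AATTAGTAGAATAGTGAAAGGCGAACCTGAAATTTAAGATCATTTATGGGATAAAAAATGAGAATCCTAA
CACAACGAGTACTGACGTTACGCCAACAATATTAAATAGACCTAAAACTGTTGTTGTACGTCACTGTCAA
CCGGGCTCTATGGACACAATCTCGGTTTACTGCGTTATTTTGGACAAGTCCCTTAACAAGCTTTCCTTGC
TGATTAAGTGTCGCTAAAATAACAGCCACCACATTGTGCTCGATCAAATAGCCTCGGTTGACAGCCTATC
TGATAATGAAAGAGCCAACTCCTCATTCACCGCTTCAGAACCTGTAGAATAACTATAATCATTCGATTAG
ATTAGTTATTTTAGCAGATCTTTCAAAAACGTTAGCTTTAAGGGAGTAAGAAATTCAAACCTATTCAATC
TCTTGTTAACGTTGAGAGCCCCATAGAAGCCACAGGCTCTGTCCTGTGCACCTCCGCTCTGAGACAAGTG
CGATTAACCCCGCTTAAACACAGACTCACGACTTTTTTCCTAGCCAACAAGTGGTCAAACATATCATCCT
GCATATTTTTTTCGGCTGAGCAATATCGTCTTTAAGTACCTGTCGTTGAAGCACTTTCGCGTCAACGATA
TATTACATTAGGAATACGAGGAGTATCGCTTCGTACGAGGCGAGATGTTGACAATTTTACAATAAGAAAT
TTTTTTAGTAGTATAATTCTAAACTATTCCATGCAGAGAGTTCGGCCTGTCCACTTTAAAGGGTACTGCT
ATTTTAGTATCATGCATTATTAACAAGTCTGTTAGCAATGTTTCACTGACTACTTTAAGTCTATAACCCC
ACCATACCCTACTGCGATACCCTACTTAATAGTGTGATCTTAACCACACTCTTATCCGGATTATCTATCT
GCCTGCATTATGTGAGGATGATTGATAAGAATTTAAATATATTCGTAAACAGACTGTCCATATTTTTTCA
GCGAGATCATGCGCTCTATATAATTGGTGAAGGCTCTGTTGAACAATTTGACAAAGGCTCACCAGAGTAA
TATGACTTACTTAACTACAGGCAAGGGTCTATCGGCTAAGGGATATCGCATACAGCAACAAATTCCGACA
AACATGTGTGGTATTGACATCCTGCAGACTCACAAAATATTTTTTAGTTTTCCATTCTAGAATACCCGCA
TATGAGGTCTCGTACGATCCTTATATATCTTACGCGAGAGACCGCAATCTGATCGGCACGGTCTTACATG
GTCTGAGTTATAGACATTGCCTGACATGCCTAGAAGACTTTAATTTCTTTAAGATAATATCAAAACGCGG
TGGTTTATAATTCGTACCCGTTAAAAAGTTTCTTCCTAGCGTTTCTTGACAGTTCGATAATTCTGTTAGG
GTCAATGAGAGCGTTACTTTAAACAGAACGTGAATGTGATCCAATGTATGAGACCAAATTACTCGACCAA
CTGCTTATTCATCACAATGTCCCCAGCTCCCATATCTCGTCGATCGACATATCCAATGACAGCCCTAGAG
GTTTTTCTGCTCACAATAGTCCATCTTTTAATACTACAACATACCAGTATTATGGGTGATAATCGTAGAG
AATCGTTGGAATCTTTTACGGTTTGAAGTTGGGTTGCCTTATTGCTCGCGATGAATGATATTTAATATAG
TACTCCACCATACTAGGATAGCGCACCTCTACAATACTATACATTTTGATTTTCGTTTTAACATAATTGG
TTTTGTTGAAGAGCTCATTAAATAAGTAATATACCCATCTTACCTCTGAAGTGTCTGTAAACGTAGAGTC
AGGGTACTTCACTTAGCGATGTTGACTCGTGGCAGCGATTCGGTCCTCAAACTGGGACAATTAAGATCTG
ACGAATCAAAAAAGCCTCTTAACAGAAATTAGGTATATAACTTCCCGAGGTAACCTTCGTGATTTAGATT
CTGACATCCAACGGTTCGGATCTGTAAGAGACTAAGGACTTATTTTCTGTTTAATGACGTTTGTCGTCCT
CACGATTAATACTTAATCCGTAGGCTAAGAAGACGTACAAAACGGTCTTGCGAATAAACTAGTTTTATAT
GCTTATAATGACAAACTTTAAAAGTCCCCCATCCGTCCTGCCTTTGAAGCCGTAAACCTGAGATTCTTTT
CACAGCTCAAAGGCTTTCGAGGTAAAAAACTTCATTTCGCTTTACGGGAGCAATCTGACCGAAGTAGGTA
GAGACAACTTTTATCCATAAGTGGATAACCAGCCATGTACAGTAATATCTCAAAACCAATCATCTGAACC
CAGAATTTGTAAACTTAATGATAGAGTCATATAATTGTCAAGCGTAAACAAATTCGTAGCACAATTAGGG
GCTTGCATAGAGCTACACAGGAGTTGCGTCCTCAAGAAAAATTAGAATTCAATACTTACACAACTCTAAA
TCCGGCTAACTTTAGGGCGTCCAAGAGAACTCATAGCTATGAGGTTCTGTATAGTTGTTAGATTGCCGCA
TCCTATCAGTATGGGCAGGTGCTAAACTCTATCGTCACCAACAGTTATGCCACCCATCCTTTTTCTTTGA
CATCAGGTTCCCAGCAGGCTTCATTGCGAGAGTGCGTTCTTAAATATTATTCAGTTAATATAACGTAAGA
TATGTACCAACCGGTTATTTATTATCCAACCCATTTTTTATTGCCTACCTCTCGTACAGTTGCACATTGT
TGAGATTACTTGTCACTCTGTCCTGAGCGGCTGCAGCATGGCTTGTATAGCAACAGGTGTTGTATATTTT
CCCTACACTTAGCGGATGGTTGATGCTCACCAATTCTAAAGAGGCATAACAGACCCTGATTGTGCTTTGG
TCACCGAGCTCAAAGCAAGCCGTTTAAGCGTGGAAAGTAATCTCAATCAGCGCAATGTTAGTTCATGCTG
TATGTCTCACAATTTGCTTATTAGTTACTGTCTGTTGCGGGCAATACATACATTCGATTGTAGAGAGACA
GAAAATAAAAGCATCCTCAAATACACCCTGTAGCTTCGAATAGGGCTGACCACAATTCATGGGCAGATTG
C
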