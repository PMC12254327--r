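GTACTCGA
TATCGGCT
TCACTGGT
TCCGCCAC
CTCGCTGC
ATGCGGAC
GTTGTACG
CTGGACCA
CCATCAGA
ACACGTGG
TTCCGGAA
TCGATGGC
AACGTTTA
CAGGACAA
CTAGCACA
AAACGCTG
GAGCGGAC
AAGGAACC
ATCGTACG
ATTAGGCC
CGGAAGAA
CGGTTGAC
AGCGGTGC
CCTGGCGT
TGAAGACT
TCCAGTCT
TTTCAGAT
GAGGCGCA
TCAGAGTG
CACGAGAA
TTTGACTC
ACCTCAGA
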