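# Synthetic training set: nested RNA structures with canonical
# basepair composition. Alternating sequence / structure lines.
ACAUUCCCGGAAGAUAUCGGGAUACA
....((((((......))))))....
GUCUCGUGGAGAAAUCUCUGUGUGCU
....((((((......))))))....
AGCCGUGUGUUGGGGUACACGCAAUA
....((((((......))))))....
GGAGAUGCAUAGGCAUCUCC
((((((((....))))))))
UAGGACAUCCAGAUGUCCUG
((((((((....))))))))
CGGGUCCGCAGUCGGACCCG
((((((((....))))))))
ACGCUGGAGAGCCAGCUAAGGGGGGUGACCCUCU
..(((((....)))))..((((......))))..
CGGACAGGUCGCUGUCCGCACUGGGUAUAGUGAG
..(((((....)))))..((((......))))..
GUCGCUCGCGGGGGUGCUGCCUGUUAGAGGGCUU
..(((((....)))))..((((......))))..
UCGGGGGUGUUAGAACAAGUGCAGCGAUACUGCACUUUCGG
(((((..(((....)))..(((((.....)))))..)))))
GCGACCUUAGCAGGCUAUACUGGUAGGGGACCAGAGGUCGC
(((((..(((....)))..(((((.....)))))..)))))
GACUGAAUCCCGGUGGGUGUGCGUGACAGGUGCAGUCAGUC
(((((..(((....)))..(((((.....)))))..)))))
UCCGAUACGGAGUCGUACCGGA
((((.((((....)))).))))
AUUGUAACGCUACCGUUACAGU
((((.((((....)))).))))
GCACUACAGAAGGCUGUGGUGC
((((.((((....)))).))))
CCGUAUAGUGGCCACACCGGGCCCUUUACGG
(((((....((((......))))...)))))
AUGGCCAUCGGAUGGGUGAAUUCAAAGCUAU
(((((....((((......))))...)))))
AUGCGGUGAUCAGCAUUAACUGGCCCCGCAU
(((((....((((......))))...)))))
AAAGGUUGACACAAGCCUUAA
..((((((...))).)))...
UAUUACGCAUUGCGCUGAGUA
..((((((...))).)))...
UCUCGCGGGGCCCGUCGAAGA
..((((((...))).)))...
CAGAUCUCGUCGUGAGAGCGAGCAUUG
(((..(((((.......)))))..)))
GGGAACUUCUUAAUAAUAGGGGCACCC
(((..(((((.......)))))..)))
CGCAUUCGGAAAAGCCAUCCGGUUGCG
(((..(((((.......)))))..)))
GGGCGGAAUGGCUUAAGCCGACGCCUCUCCAGGCAACCGCCCAU
((((((..((((....))))..((((....))))..))))))..
GGGACCAAUCCGCACCCGGAAUCGCCAUGAGGCGCAGGUCCCAC
((((((..((((....))))..((((....))))..))))))..
UACAGUGGUUUGUGUUCAAAGACCAUAUUCAUGGUCACUGUGCG
((((((..((((....))))..((((....))))..))))))..
AAAGUUUGGCUCUCUAGUGGGGGCGUCAAUUACC
.....(((((((((....)))))..)))).....
GUUUUCAGUCGGGCACACGCUCGAUACUGGAUGU
.....(((((((((....)))))..)))).....
UUAUCUGGCGGAGAACGCUCUCUACGCUGAAAGA
.....(((((((((....)))))..)))).....
UCCCCGUAGACGACUUACUGGUCGUGAUCUGCAAAAGGCAGGUUGGGGG
((((.....((((((....))))))..((((.......))))...))))
UUGGAAAACCCGAAUAGAGGUUCGGAUUUCUCGCAUAUGGAAAGACCAA
((((.....((((((....))))))..((((.......))))...))))
AGCGAUAGCCCGGCAUUCAUGCCGGAUGGAUGUCGUAAAUCUGGGCGCU
((((.....((((((....))))))..((((.......))))...))))
GUACCUAGGGGUACUUAGAGGUAC
(((((((((....))))..)))))
CGUUAGAUCGACCGAUUAGUAAUG
(((((((((....))))..)))))
ACAAGGCUGGGAAUAGCUACUUGU
(((((((((....))))..)))))
GGAAAUCUCCGAGCAGAGGCUCGGGGGUUUAU
..(((((.((((((....)))))).)))))..
GACUUUGCUCCUUGCUUACAAGGGUCGAAGUU
..(((((.((((((....)))))).)))))..
UGCCAGGAUAGUGCUAAUGCACUAACCUGGUG
..(((((.((((((....)))))).)))))..
CUGCGGUCGGCCGUAAG
((((((....)))).))
AUAGACGGUAGUCUUAU
((((((....)))).))
CGUGAGGGAAUUCAUCG
((((((....)))).))
GGUAAGGGCACGUAUAAGUGUGCUCCAUACCCGCUCUUUAUUGCAAAGAG
(((..((((((((....))))))))...)))..((((((.....))))))
UGCGUAGCACCCGUAAAUGGGUGUUAGUGCAACAAGGGGAUCUUCCCCUU
(((..((((((((....))))))))...)))..((((((.....))))))
ACGAUUGGCGGGGACUUCCCCGCUAGUACGUUAGGGCGAGACCAUUGCCC
(((..((((((((....))))))))...)))..((((((.....))))))
AUUGGUUUGCCAAUAACAAUUAGCAGGCCGCC
..((((((((.(((....))).))))))))..
AAUUCGCUGUAGGUAUAUAUCAACAGUGGAUA
..((((((((.(((....))).))))))))..
AAGACUAGCGACCAAUACUGGGCGUUGGUCGA
..((((((((.(((....))).))))))))..
UAUGCUUAAGCAUA
(((((....)))))
UAACUAAGAAGUUG
(((((....)))))
GGCCGAGCUCGGUC
(((((....)))))
GCCCCUCCGGAAGCUUUAUCAGGCGCCCGGAGGGGC
((((((((((..((((....))))..))))))))))
GGCGGGCGCUCCGUUGAAGUCAACCUAGUGCCCGUC
((((((((((..((((....))))..))))))))))
GGGAUAUGACCCGACGCACGCGUCGUGUCGUAUCCC
((((((((((..((((....))))..))))))))))
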