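>NisA nisin A precursor prepropeptide (type 1 exemplar)
MSTKDFNLDLVSVSKKDSGASPRITSISLCTPGCKTGALMGCNMKTATCHCSIHVSK
>SpaS subtilin precursor prepropeptide
MSKFDDFDLDVVKVSKQDSKITPQWKSESLCTPGCVTGALQTCFLQTLTCNCKISK
>EpiA epidermin precursor prepropeptide
MEAVKEKNDLFNLDVKVNAKESNDSGAEPRIASKFICTPGCAKTGSFNSYCC
>GdmA gallidermin precursor prepropeptide
MEAVKEKNELFDLDVKVNAKESNDSGAEPRIASKFLCTPGCAKTGSFNSYCC
>PepA Pep5 precursor prepropeptide
MKNNKNLFDLEIKKETSQNTDELEPQTAGPAIRASVKQCQKTLKATRLFTVSCKGKNGCK
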