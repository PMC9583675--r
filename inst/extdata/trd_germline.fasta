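>TRDV2|V CDR3-proximal region, conserved Cys codon to segment 3' end (IMGT-derived)
TGTGCCTGTGACACC
>TRDD1|D full segment (IMGT-derived)
GAAATAGT
>TRDD2|D full segment (IMGT-derived)
CCTTCCTAC
>TRDD3|D full segment (IMGT-derived)
ACTGGGGGATACG
>TRDJ1|J CDR3-proximal region, segment 5' end through conserved Phe codon (IMGT-derived)
ACACCGATAAACTCATCTTT
>TRDJ2|J CDR3-proximal excerpt through conserved Phe codon (reconstructed from canonical tail motif)
CTCACCGCGCAGCTCTTCTTT
>TRDJ3|J CDR3-proximal excerpt through conserved Phe codon (reconstructed from canonical tail motif)
TCCTGGGACACCCGACAGATGTTTTTC
>TRDJ4|J CDR3-proximal excerpt through conserved Phe codon (reconstructed from canonical tail motif)
CGCCCTCTCATCTTT
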