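>PRKDC_SYNTHETIC synthetic stand-in emulating the DNA-PK remnant-site context (site K65 in a 57-residue tryptic peptide)
CGAQFICYLFGWIYEPFGVGDNEAQSYNFFIVGFDIECIRHHDEDHQNGACLFVQPTPSEMGWGKDICIGWNNFFLQIVMCTPSMNHAVWGPMSQQRACWWYHYSGMCCIDHHHYDQTPADDKSWDDQGQCCGEWWAGEVSCFSCPCVCACAD
>SP100_SYNTHETIC synthetic stand-in emulating the Sp100 remnant-site context (site K33 in a 6-residue tryptic peptide)
NMEGVTAGYHMQLPPEIYYMAHSPVGSYDRHAKWMRCSIDQFYLCGIPSHQPPSFQCTHYPQILWTQGDEDWMFHSKAWAFVHTLTGIL
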