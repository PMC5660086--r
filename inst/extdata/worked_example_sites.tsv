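# Synthetic worked-example remnant sites (accessions are synthetic stand-ins,
# see synthetic_worked_examples.fasta)
accession	position	note
PRKDC_SYNTHETIC	65	remnant site inside a tryptic-site-poor region
SP100_SYNTHETIC	33	remnant site inside a short tryptic peptide
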