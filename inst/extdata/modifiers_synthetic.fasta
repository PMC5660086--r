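>SUMO1 synthetic mature C-terminal segment (T precedes the attachment diglycine; no tryptic site near the C terminus)
ADNHTPKELGMEEEDVIEVYQEQTGG
>SUMO2 synthetic mature C-terminal segment (T precedes the attachment diglycine)
NDTPAQLEMEDEDTIDVFQQQTGG
>SUMO3 synthetic mature C-terminal segment (T precedes the attachment diglycine)
DTPAQLEMEDEDTIDVFQQQTGG
>SUMO4 synthetic mature C-terminal segment (T precedes the attachment diglycine)
ETPAQLEMEDEDTIDVYQEQTGG
>Ub synthetic mature C-terminal segment (R precedes the attachment diglycine)
ESTLHLVLRLRGG
>Nedd8 synthetic mature C-terminal segment (R precedes the attachment diglycine)
SVLHLVLALRGG
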