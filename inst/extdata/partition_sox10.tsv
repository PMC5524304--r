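cne	species	in_a	in_b	tetrapod_shared
cne01	zebrafish	FALSE	TRUE	FALSE
cne01	medaka	FALSE	TRUE	FALSE
cne01	tilapia	FALSE	TRUE	FALSE
cne01	platyfish	FALSE	TRUE	FALSE
cne01	tetraodon	FALSE	TRUE	FALSE
cne01	fugu	FALSE	TRUE	FALSE
cne02	zebrafish	FALSE	TRUE	FALSE
cne02	medaka	FALSE	TRUE	FALSE
cne02	tilapia	FALSE	TRUE	FALSE
cne02	platyfish	FALSE	TRUE	FALSE
cne02	tetraodon	FALSE	TRUE	FALSE
cne02	fugu	FALSE	TRUE	FALSE
cne03	zebrafish	TRUE	FALSE	FALSE
cne03	medaka	TRUE	FALSE	FALSE
cne03	tilapia	TRUE	FALSE	FALSE
cne03	platyfish	FALSE	FALSE	FALSE
cne03	tetraodon	FALSE	FALSE	FALSE
cne03	fugu	TRUE	FALSE	FALSE
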