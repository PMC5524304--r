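cne	species	in_a	in_b	tetrapod_shared
cne01	zebrafish	FALSE	FALSE	TRUE
cne01	medaka	FALSE	FALSE	TRUE
cne01	tilapia	FALSE	TRUE	TRUE
cne01	platyfish	FALSE	FALSE	TRUE
cne01	tetraodon	FALSE	TRUE	TRUE
cne01	fugu	FALSE	TRUE	TRUE
cne02	zebrafish	FALSE	TRUE	TRUE
cne02	medaka	FALSE	TRUE	TRUE
cne02	tilapia	FALSE	TRUE	TRUE
cne02	platyfish	FALSE	TRUE	TRUE
cne02	tetraodon	FALSE	TRUE	TRUE
cne02	fugu	FALSE	TRUE	TRUE
cne03	zebrafish	FALSE	FALSE	FALSE
cne03	medaka	FALSE	TRUE	FALSE
cne03	tilapia	FALSE	TRUE	FALSE
cne03	platyfish	FALSE	FALSE	FALSE
cne03	tetraodon	FALSE	FALSE	FALSE
cne03	fugu	FALSE	TRUE	FALSE
cne04	zebrafish	FALSE	TRUE	FALSE
cne04	medaka	FALSE	TRUE	FALSE
cne04	tilapia	FALSE	FALSE	FALSE
cne04	platyfish	FALSE	TRUE	FALSE
cne04	tetraodon	FALSE	FALSE	FALSE
cne04	fugu	FALSE	FALSE	FALSE
cne05	zebrafish	FALSE	TRUE	FALSE
cne05	medaka	FALSE	TRUE	FALSE
cne05	tilapia	FALSE	TRUE	FALSE
cne05	platyfish	FALSE	FALSE	FALSE
cne05	tetraodon	FALSE	TRUE	FALSE
cne05	fugu	FALSE	FALSE	FALSE
cne06	zebrafish	FALSE	TRUE	FALSE
cne06	medaka	FALSE	FALSE	FALSE
cne06	tilapia	FALSE	TRUE	FALSE
cne06	platyfish	FALSE	TRUE	FALSE
cne06	tetraodon	FALSE	TRUE	FALSE
cne06	fugu	FALSE	FALSE	FALSE
cne07	zebrafish	FALSE	TRUE	FALSE
cne07	medaka	FALSE	TRUE	FALSE
cne07	tilapia	FALSE	FALSE	FALSE
cne07	platyfish	FALSE	TRUE	FALSE
cne07	tetraodon	FALSE	TRUE	FALSE
cne07	fugu	FALSE	TRUE	FALSE
cne08	zebrafish	FALSE	TRUE	FALSE
cne08	medaka	FALSE	FALSE	FALSE
cne08	tilapia	FALSE	TRUE	FALSE
cne08	platyfish	FALSE	FALSE	FALSE
cne08	tetraodon	FALSE	FALSE	FALSE
cne08	fugu	FALSE	TRUE	FALSE
cne09	zebrafish	FALSE	FALSE	FALSE
cne09	medaka	TRUE	FALSE	FALSE
cne09	tilapia	TRUE	FALSE	FALSE
cne09	platyfish	TRUE	FALSE	FALSE
cne09	tetraodon	TRUE	FALSE	FALSE
cne09	fugu	TRUE	FALSE	FALSE
cne10	zebrafish	TRUE	TRUE	FALSE
cne10	medaka	FALSE	FALSE	FALSE
cne10	tilapia	TRUE	FALSE	FALSE
cne10	platyfish	TRUE	TRUE	FALSE
cne10	tetraodon	TRUE	FALSE	FALSE
cne10	fugu	TRUE	TRUE	FALSE
cne11	zebrafish	TRUE	TRUE	FALSE
cne11	medaka	FALSE	TRUE	FALSE
cne11	tilapia	TRUE	TRUE	FALSE
cne11	platyfish	TRUE	FALSE	FALSE
cne11	tetraodon	TRUE	TRUE	FALSE
cne11	fugu	TRUE	TRUE	FALSE
cne12	zebrafish	FALSE	FALSE	FALSE
cne12	medaka	FALSE	FALSE	FALSE
cne12	tilapia	FALSE	FALSE	FALSE
cne12	platyfish	FALSE	FALSE	FALSE
cne12	tetraodon	FALSE	FALSE	FALSE
cne12	fugu	FALSE	FALSE	FALSE
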