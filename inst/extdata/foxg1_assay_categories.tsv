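variant_id	expression_category	repression_status	migration_category
WT	normal	intact	cp_low
Q86Dfs*34	very_low	LOF	cp_high
Q86Rfs*106	very_low	LOF	cp_high
E136X	very_low	LOF	cp_high
P182Q	normal	intact	cp_low
N187K	normal	LOF	cp_low
I194S	low	LOF	cp_high
F215L	low	partial_LOF	cp_mid
R230H	very_low	LOF	cp_high
L235H	normal	intact	cp_high
G252V	very_low	LOF	cp_high
G252D	high	partial_LOF	cp_mid
W255Lfs*156	very_low	LOF	cp_high
Y307X	high	intact	cp_low
Y416X	high	intact	cp_high
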