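pfam	category
PF00150	cellulases
PF00759	cellulases
PF01341	cellulases
PF00840	cellulases
PF00331	hemicellulases
PF00457	hemicellulases
PF02156	hemicellulases
PF07745	hemicellulases
PF00128	starch-degrading
PF02806	starch-degrading
PF00723	starch-degrading
PF02056	starch-degrading
PF00933	oligosaccharide hydrolases
PF00232	oligosaccharide hydrolases
PF02836	oligosaccharide hydrolases
PF01301	oligosaccharide hydrolases
PF01095	pectin-degrading
PF00544	pectin-degrading
PF00704	chitinases
PF00728	amino-sugar hydrolases
PF01522	carbohydrate esterases
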