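canonical_name,category,synonyms,components,component_strengths
insulin glargine,INSULIN,lantus|basaglar|toujeo|semglee|glargine|rezvoglar,,
insulin detemir,INSULIN,levemir|detemir,,
insulin degludec,INSULIN,tresiba|degludec,,
insulin lispro,INSULIN,humalog|admelog|lyumjev|lispro,,
insulin aspart,INSULIN,novolog|fiasp|aspart,,
insulin glulisine,INSULIN,apidra|glulisine,,
insulin regular,INSULIN,humulin r|novolin r|regular insulin,,
insulin nph,INSULIN,humulin n|novolin n|nph|nph insulin|isophane insulin,,
insulin 70/30,INSULIN,humulin 70/30|novolin 70/30|novolog mix 70/30,,
metformin,METFORMIN,glucophage|metformin hcl|metformin hydrochloride|mtf,,
metformin er,METFORMIN,glucophage xr|glumetza|fortamet|metformin xr|metformin hcl er,,
metformin oral solution,METFORMIN,riomet,,
glipizide,NON_INSULIN_OTHER,glucotrol|glucotrol xl|glipizide er,,
glyburide,NON_INSULIN_OTHER,diabeta|micronase|glynase|glibenclamide,,
glimepiride,NON_INSULIN_OTHER,amaryl,,
sitagliptin,NON_INSULIN_OTHER,januvia,,
saxagliptin,NON_INSULIN_OTHER,onglyza,,
linagliptin,NON_INSULIN_OTHER,tradjenta,,
alogliptin,NON_INSULIN_OTHER,nesina,,
empagliflozin,NON_INSULIN_OTHER,jardiance,,
dapagliflozin,NON_INSULIN_OTHER,farxiga,,
canagliflozin,NON_INSULIN_OTHER,invokana,,
ertugliflozin,NON_INSULIN_OTHER,steglatro,,
liraglutide,NON_INSULIN_OTHER,victoza|saxenda,,
semaglutide,NON_INSULIN_OTHER,ozempic|rybelsus|wegovy,,
dulaglutide,NON_INSULIN_OTHER,trulicity,,
exenatide,NON_INSULIN_OTHER,byetta|bydureon|bydureon bcise,,
tirzepatide,NON_INSULIN_OTHER,mounjaro|zepbound,,
pioglitazone,NON_INSULIN_OTHER,actos,,
rosiglitazone,NON_INSULIN_OTHER,avandia,,
repaglinide,NON_INSULIN_OTHER,prandin,,
nateglinide,NON_INSULIN_OTHER,starlix,,
acarbose,NON_INSULIN_OTHER,precose,,
miglitol,NON_INSULIN_OTHER,glyset,,
sitagliptin-metformin,NON_INSULIN_OTHER,janumet|janumet xr,sitagliptin|metformin,50|500
empagliflozin-metformin,NON_INSULIN_OTHER,synjardy|synjardy xr,empagliflozin|metformin,5|500
dapagliflozin-metformin,NON_INSULIN_OTHER,xigduo xr,dapagliflozin|metformin,5|500
canagliflozin-metformin,NON_INSULIN_OTHER,invokamet|invokamet xr,canagliflozin|metformin,50|500
linagliptin-metformin,NON_INSULIN_OTHER,jentadueto|jentadueto xr,linagliptin|metformin,2.5|500
saxagliptin-metformin,NON_INSULIN_OTHER,kombiglyze xr,saxagliptin|metformin,5|500
glyburide-metformin,NON_INSULIN_OTHER,glucovance,glyburide|metformin,2.5|500
glipizide-metformin,NON_INSULIN_OTHER,metaglip,glipizide|metformin,2.5|250
pioglitazone-metformin,NON_INSULIN_OTHER,actoplus met|actoplus met xr,pioglitazone|metformin,15|500
empagliflozin-linagliptin,NON_INSULIN_OTHER,glyxambi,empagliflozin|linagliptin,10|5
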