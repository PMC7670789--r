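code,country,basket_printed,pool_size,active_count,min_required,rule,m,k,caps,revision_months
AT,Austria,26,26,26,14,average,,,,
BE,Belgium,27,27,27,1,average,,,,
BG,Bulgaria,17,17,17,1,minimum,,,,6
HR,Croatia,3 out of 5,5,3,2,average,,,,12
CY,Cyprus,4 out of 10,10,4,1,average,,,,12
CZ,Czech Republic,19,19,19,3,avg_lowest,3,,,36
EE,Estonia,3,3,3,1,minimum,,,,12
FI,Finland,29,29,29,1,average,,,,60
FR,France,4,4,4,1,average,,,,60
DE,Germany,15,15,15,1,average,,,,
GR,Greece,26,26,26,3,avg_lowest,3,,,3
HU,Hungary,31,30,30,3,minimum,,,,
IS,Iceland,4,4,4,3,average,,,,24
IE,Ireland,9,9,9,1,average,,,,36
IT,Italy,25,25,25,1,minimum,,,,24
LV,Latvia,7,7,7,1,kth_lowest_capped,,3,LT;EE,24
LT,Lithuania,8,8,8,1,average,,,,12
LU,Luxembourg,1,1,1,1,minimum,,,,12
MT,Malta,12,12,12,3,average,,,,18
NL,Netherlands,4,4,4,2,average,,,,6
NO,Norway,9,9,9,1,avg_lowest,3,,,12
PL,Poland,31,30,30,1,average,,,,24
PT,Portugal,3,3,3,1,average,,,,12
RO,Romania,12,12,12,1,minimum,,,,60
SK,Slovakia,27,27,27,1,avg_lowest,3,,,6
SI,Slovenia,3,3,3,1,minimum,,,,6
ES,Spain,18,18,18,1,minimum,,,,12
CH,Switzerland,6,6,6,1,average,,,,36
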