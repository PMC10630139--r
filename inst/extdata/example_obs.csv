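"","condition","cell_type"
"cell1","ctrl","state2"
"cell2","stim","state1"
"cell3","stim","state1"
"cell4","stim","state2"
"cell5","stim","state1"
"cell6","ctrl","state2"
"cell7","stim","state1"
"cell8","ctrl","state2"
"cell9","ctrl","state2"
"cell10","stim","state2"
"cell11","ctrl","state2"
"cell12","stim","state1"
"cell13","ctrl","state2"
"cell14","stim","state2"
"cell15","ctrl","state2"
"cell16","stim","state1"
"cell17","stim","state2"
"cell18","ctrl","state1"
"cell19","ctrl","state2"
"cell20","ctrl","state2"
"cell21","ctrl","state1"
"cell22","ctrl","state2"
"cell23","ctrl","state2"
"cell24","ctrl","state2"
"cell25","ctrl","state1"
"cell26","stim","state1"
"cell27","stim","state2"
"cell28","stim","state2"
"cell29","stim","state2"
"cell30","stim","state1"
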