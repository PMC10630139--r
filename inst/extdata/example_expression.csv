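"","conf_g1","conf_g2","conf_g3","conf_g4","conf_g5","conf_g6","conf_g7","conf_g8","conf_g9","conf_g10","conf_g11","conf_g12","conf_g13","conf_g14","resp_g1","resp_g2","resp_g3","resp_g4","resp_g5","resp_g6"
"cell1",0,5,0,0,2,0,1,0,6,1,1,7,1,5,0,3,2,2,5,1
"cell2",2,6,2,9,4,3,3,5,1,7,1,2,3,7,0,32,2,4,9,1
"cell3",3,2,3,4,1,2,0,2,4,4,3,1,3,3,0,0,1,0,2,5
"cell4",2,3,2,4,1,1,2,5,3,4,3,4,3,4,0,1,4,2,1,0
"cell5",0,2,4,0,0,1,5,7,1,2,1,0,1,3,0,2,1,1,2,0
"cell6",0,2,0,3,0,4,2,1,1,1,1,4,3,3,0,3,0,2,4,0
"cell7",0,1,3,1,5,4,7,5,5,0,3,0,3,9,0,1,5,0,3,1
"cell8",1,4,2,3,1,3,1,2,1,7,2,3,1,8,0,1,8,0,2,0
"cell9",3,2,1,1,4,4,3,1,7,2,1,3,1,5,0,0,3,0,4,2
"cell10",0,3,3,1,3,2,2,4,1,5,4,6,1,3,0,30,5,7,2,2
"cell11",3,2,4,3,1,3,7,5,7,2,0,10,4,2,1,5,3,6,4,0
"cell12",0,1,1,3,1,6,3,1,2,2,3,3,1,2,1,0,0,1,4,0
"cell13",2,1,4,1,0,6,2,3,5,3,1,4,1,2,1,4,2,1,5,1
"cell14",1,2,2,2,1,5,4,1,5,0,3,1,1,2,0,15,4,3,6,1
"cell15",1,1,5,2,2,1,2,3,5,2,3,3,4,6,0,1,3,2,2,2
"cell16",0,1,1,1,3,2,4,5,2,1,2,0,2,6,0,0,3,0,3,0
"cell17",1,1,2,4,2,3,3,7,5,3,1,0,2,3,1,18,1,16,2,2
"cell18",1,4,0,0,0,2,1,4,1,7,2,1,1,3,0,6,4,0,7,2
"cell19",1,1,1,6,1,9,1,3,3,1,2,3,1,2,1,0,1,4,2,3
"cell20",3,4,2,5,2,1,5,3,6,5,5,4,1,1,0,4,1,1,4,2
"cell21",5,5,1,1,2,1,4,3,0,1,2,0,4,2,0,0,1,3,2,4
"cell22",2,1,1,1,2,3,1,5,3,3,2,1,2,4,0,3,3,1,3,0
"cell23",0,6,0,3,1,4,5,1,7,2,4,5,1,3,0,2,3,4,5,2
"cell24",0,3,2,1,2,4,3,8,4,12,7,8,6,4,1,1,1,2,8,3
"cell25",0,2,3,1,3,5,4,1,3,3,2,0,0,5,1,2,2,1,4,0
"cell26",2,6,3,2,4,3,1,6,6,3,1,0,1,8,0,17,3,6,5,3
"cell27",3,1,5,0,1,0,1,1,8,0,1,1,1,3,0,36,4,2,2,1
"cell28",0,0,1,3,2,2,5,2,3,5,0,3,1,6,1,22,2,4,3,4
"cell29",2,1,1,2,2,4,4,2,2,3,1,8,6,2,1,19,3,10,0,2
"cell30",0,4,2,1,0,3,3,1,5,2,0,2,4,8,0,18,2,3,0,0
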