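tribe,genus,species_total,species_total_listed,species_observed
Ampelopsideae,Ampelopsis,18,18,13
Ampelopsideae,Nekemias,9,NA,0
Ampelopsideae,Rhoicissus,14,14,2
Ampelopsideae,Clematicissus,6,NA,0
Cisseae,Cissus,300,300,33
Cayratieae,Cayratia,25,60,7
Cayratieae,Causonis,30,9,1
Cayratieae,Acareosperma,1,NA,0
Cayratieae,Afrocayratia,7,NA,0
Cayratieae,Cyphostemma,200,200,3
Cayratieae,Pseudocayratia,5,5,3
Cayratieae,Tetrastigma,100,100,26
Parthenocisseae,Parthenocissus,14,14,9
Parthenocisseae,Yua,2,2,2
Viteae,Ampelocissus,115,115,13
Viteae,Vitis,75,75,19
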