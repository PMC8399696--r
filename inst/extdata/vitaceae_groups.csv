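group_id,label,species,refs
I,Lenses,Cissus quadrangularis,B44
I,Lenses,Cissus sterculiifolia,B31
I,Lenses,Tetrastigma petraeum,B52
II,Superellipses,Ampelocissus bravoi,B42
II,Superellipses,Cissus reniformis,B31;B41
II,Superellipses,Cyphostemma elephantopus,B49
II,Superellipses,Cyphostemma laza,B31
II,Superellipses,Tetrastigma campylocarpum,B52
II,Superellipses,Tetrastigma caudatum,B52
II,Superellipses,Tetrastigma henryi,B52
III,Elongated water drops,Ampelopsis arborea,B37
III,Elongated water drops,Cayratia imerinensis,B47
III,Elongated water drops,Cissus aralioides,B35;B40
III,Elongated water drops,Cissus cornifolia,B40
III,Elongated water drops,Cissus erosa,B43
III,Elongated water drops,Cissus integrifolia,B40;B42
III,Elongated water drops,Cissus petiolata,B40
III,Elongated water drops,Cissus pileata,B40
III,Elongated water drops,Cissus populnea,B40
III,Elongated water drops,Cissus verticillata,B31;B41;B42;B45
III,Elongated water drops,Cissus sciaphila,B40
III,Elongated water drops,Cissus smithiana,B40
III,Elongated water drops,Cissus willardii,B42
III,Elongated water drops,Cyphostemma junceum,B31
III,Elongated water drops,Vitis vulpina,B59;B62
IV,"Water drops, normal or rounded",Ampelopsis bodinieri,B36
IV,"Water drops, normal or rounded",Ampelopsis glandulosa,B36;B39
IV,"Water drops, normal or rounded",Ampelopsis humulifolia,B36
IV,"Water drops, normal or rounded",Cayratia cheniana,B46
IV,"Water drops, normal or rounded",Cissus campestris,B31;B41;B42
IV,"Water drops, normal or rounded",Cissus fuliginea,B31
IV,"Water drops, normal or rounded",Cissus tuberosa,B42
IV,"Water drops, normal or rounded",Cissus granulosa,B31
IV,"Water drops, normal or rounded",Parthenocissus dalzielii,B36
IV,"Water drops, normal or rounded",Tetrastigma triphyllum,B31;B52
IV,"Water drops, normal or rounded",Vitis amurensis,B45;B56
IV,"Water drops, normal or rounded",Vitis labrusca,B45;B54;B59
IV,"Water drops, normal or rounded",Vitis palmata,B60
IV,"Water drops, normal or rounded",Vitis rupestris,B45
V,Heart curves normal or rounded,Ampelopsis aconitifolia,B36
V,Heart curves normal or rounded,Ampelopsis chaffanjoni,B36
V,Heart curves normal or rounded,Ampelopsis cordata,B38
V,Heart curves normal or rounded,Ampelopsis japonica,B36
V,Heart curves normal or rounded,Parthenocissus heptaphylla,B31
V,Heart curves normal or rounded,Parthenocissus heterophylla,B36
V,Heart curves normal or rounded,Parthenocissus henryana,B36
V,Heart curves normal or rounded,Parthenocissus himalayana,B52;B53
V,Heart curves normal or rounded,Parthenocissus quinquefolia,B54
V,Heart curves normal or rounded,Parthenocissus vitacea,B31
V,Heart curves normal or rounded,Parthenocissus tricuspidata,B36;B37;B45
V,Heart curves normal or rounded,Rhoicissus revoilii,B31
V,Heart curves normal or rounded,Tetrastigma lanceolarium,B30
V,Heart curves normal or rounded,Vitis cinerea,B57
V,Heart curves normal or rounded,Vitis flexuosa,B54
V,Heart curves normal or rounded,Vitis lanatoides,B58
V,Heart curves normal or rounded,Vitis latisulcata,B58
V,Heart curves normal or rounded,Vitis tsoi,B31;B41
V,Heart curves normal or rounded,Vitis wilsoniae,B31;B41
VI,Elongated Heart curves,Ampelocissus acapulcensis,B30
VI,Elongated Heart curves,Cissus oligocarpa,B31
VI,Elongated Heart curves,Vitis eolabrusca,B54
VI,Elongated Heart curves,Vitis grayensis,B58
VI,Elongated Heart curves,Vitis pseudorotundifolia,B54
VI,Elongated Heart curves,Vitis tiliifolia,B61
VII,Other elongated types,Ampelopsis megalophylla,B31;B36
VII,Other elongated types,Causonis sp.,B46
VII,Other elongated types,Cayratia saponaria,B31
VII,Other elongated types,Cissus trianae,B31
VII,Other elongated types,Cissus hypoglauca,B31
VII,Other elongated types,Parthenocissus laetevirens,B36
VII,Other elongated types,Tetrastigma hypoglaucum,B52
VII,Other elongated types,Vitis aestivalis,B55
VII,Other elongated types,Vitis rotundifolia,B31;B41;B54
VII,Other elongated types,Yua austro-orientalis,B31
VII,Other elongated types,Yua chinensis,B31
VIII,Heart curves of the Cayratia and Pseudocayratia types,Cayratia japonica,B31;B48
VIII,Heart curves of the Cayratia and Pseudocayratia types,Cayratia sp. [African],B46
VIII,Heart curves of the Cayratia and Pseudocayratia types,Pseudocayratia dichromocarpa,B50
VIII,Heart curves of the Cayratia and Pseudocayratia types,Pseudocayratia pengiana,B50
VIII,Heart curves of the Cayratia and Pseudocayratia types,Pseudocayratia speciosa,B50;B52
VIII,Heart curves of the Cayratia and Pseudocayratia types,Tetrastigma formosanum,B51
VIII,Heart curves of the Cayratia and Pseudocayratia types,Tetrastigma pedunculare,B31;B51;B52
IX,Heart curves of the SqHC type of Ampelocissus and Ampelopsis,Ampelocissus bombycina,B30
IX,Heart curves of the SqHC type of Ampelocissus and Ampelopsis,Ampelocissus cavicaulis,B30
IX,Heart curves of the SqHC type of Ampelocissus and Ampelopsis,Ampelocissus erdvendbergiana,B30
IX,Heart curves of the SqHC type of Ampelocissus and Ampelopsis,Ampelocissus grantii,B30
IX,Heart curves of the SqHC type of Ampelocissus and Ampelopsis,Ampelocissus javalensis,B30;B42
IX,Heart curves of the SqHC type of Ampelocissus and Ampelopsis,Ampelocissus latifolia,B30
IX,Heart curves of the SqHC type of Ampelocissus and Ampelopsis,Ampelocissus macrocirrha,B30
IX,Heart curves of the SqHC type of Ampelocissus and Ampelopsis,Ampelocissus martinii,B42
IX,Heart curves of the SqHC type of Ampelocissus and Ampelopsis,Ampelocissus obtusata,B30
IX,Heart curves of the SqHC type of Ampelocissus and Ampelopsis,Ampelocissus ochracea,B30
IX,Heart curves of the SqHC type of Ampelocissus and Ampelopsis,Ampelocissus robinsonii,B30
IX,Heart curves of the SqHC type of Ampelocissus and Ampelopsis,Ampelopsis cantoniensis,B31;B36
IX,Heart curves of the SqHC type of Ampelocissus and Ampelopsis,Ampelopsis delavayana,B31
IX,Heart curves of the SqHC type of Ampelocissus and Ampelopsis,Ampelopsis denudata,B30
IX,Heart curves of the SqHC type of Ampelocissus and Ampelopsis,Ampelopsis grossedentata,B31
X,Elongated Superellipse-heart curves,Cissus elongata,B40
X,Elongated Superellipse-heart curves,Cissus penninervis,B31
X,Elongated Superellipse-heart curves,Rhoicissus rhomboidea,B31
X,Elongated Superellipse-heart curves,Tetrastigma hemsleyanum,B31;B52
X,Elongated Superellipse-heart curves,Tetrastigma jinghongense,B52
X,Elongated Superellipse-heart curves,Tetrastigma laoticum,B52
X,Elongated Superellipse-heart curves,Tetrastigma cauliflorum,B52
X,Elongated Superellipse-heart curves,Tetrastigma dichotomum,B51
X,Elongated Superellipse-heart curves,Tetrastigma harmandi,B31
X,Elongated Superellipse-heart curves,Tetrastigma pachyllylum,B52
X,Elongated Superellipse-heart curves,Tetrastigma kwangsiense,B30;B31
X,Elongated Superellipse-heart curves,Tetrastigma obovatum,B51;B52
X,Elongated Superellipse-heart curves,Tetrastigma obtectum,B51;B52
X,Elongated Superellipse-heart curves,Tetrastigma retinervum,B51
X,Elongated Superellipse-heart curves,Tetrastigma serrulatum,B52
X,Elongated Superellipse-heart curves,Tetrastigma sichouense,B52
UNDEFINED,Undefined,Cayratia geniculata,B31
UNDEFINED,Undefined,Cissus antarctica,B31
UNDEFINED,Undefined,Cissus barbeyana,B40
UNDEFINED,Undefined,Cissus bosseri,B40
UNDEFINED,Undefined,Cissus cactiformis,B40
UNDEFINED,Undefined,Cissus descoingsii,B31;B41
UNDEFINED,Undefined,Cissus diffusiflora,B40
UNDEFINED,Undefined,Cissus floribunda,B40
UNDEFINED,Undefined,Cissus hastata,B40
UNDEFINED,Undefined,Cissus leucophlea,B40
UNDEFINED,Undefined,Cissus repens,B40
UNDEFINED,Undefined,Cissus subtetragona,B40
UNDEFINED,Undefined,Tetrastigma delavayi,B52
UNDEFINED,Undefined,Tetrastigma rumicispermum,B31;B51;B52
UNDEFINED,Undefined,Tetrastigma thorsborneorum,B52
UNDEFINED,Undefined,Tetrastigma xishuangbannaense,B31;B52
UNDEFINED,Undefined,Vitis brandoniana,B54
UNDEFINED,Undefined,Vitis rostrata,B54
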