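tribe,genus,species,refs
Ampelopsideae,Ampelopsis,Ampelopsis aconitifolia,B36
Ampelopsideae,Ampelopsis,Ampelopsis arborea,B37
Ampelopsideae,Ampelopsis,Ampelopsis bodinieri,B36
Ampelopsideae,Ampelopsis,Ampelopsis cantoniensis,B31;B36
Ampelopsideae,Ampelopsis,Ampelopsis cordata,B38
Ampelopsideae,Ampelopsis,Ampelopsis chaffanjoni,B36
Ampelopsideae,Ampelopsis,Ampelopsis delavayana,B31
Ampelopsideae,Ampelopsis,Ampelopsis denudata,B30
Ampelopsideae,Ampelopsis,Ampelopsis glandulosa,B39
Ampelopsideae,Ampelopsis,Ampelopsis grossedentata,B31
Ampelopsideae,Ampelopsis,Ampelopsis humulifolia,B36
Ampelopsideae,Ampelopsis,Ampelopsis japonica,B36
Ampelopsideae,Ampelopsis,Ampelopsis megalophylla,B31;B36
Ampelopsideae,Rhoicissus,Rhoicissus revoilii,B31
Ampelopsideae,Rhoicissus,Rhoicissus rhomboidea,B31
Cisseae,Cissus,Cissus antarctica,B31
Cisseae,Cissus,Cissus aralioides,B35;B40
Cisseae,Cissus,Cissus barbeyana,B40
Cisseae,Cissus,Cissus bosseri,B40
Cisseae,Cissus,Cissus cactiformis,B40
Cisseae,Cissus,Cissus campestris,B31;B41;B42
Cisseae,Cissus,Cissus cornifolia,B40
Cisseae,Cissus,Cissus descoingsii,B31;B41
Cisseae,Cissus,Cissus diffusiflora,B40
Cisseae,Cissus,Cissus elongata,B40
Cisseae,Cissus,Cissus erosa,B43
Cisseae,Cissus,Cissus floribunda,B40
Cisseae,Cissus,Cissus fuliginea,B31
Cisseae,Cissus,Cissus granulosa,B31
Cisseae,Cissus,Cissus hastata,B40
Cisseae,Cissus,Cissus hypoglauca,B31
Cisseae,Cissus,Cissus integrifolia,B40;B42
Cisseae,Cissus,Cissus leucophlea,B40
Cisseae,Cissus,Cissus penninervis,B31
Cisseae,Cissus,Cissus petiolata,B40
Cisseae,Cissus,Cissus pileata,B40
Cisseae,Cissus,Cissus populnea,B40
Cisseae,Cissus,Cissus quadrangularis,B44
Cisseae,Cissus,Cissus reniformis,B31;B41
Cisseae,Cissus,Cissus repens,B40
Cisseae,Cissus,Cissus sciaphila,B40
Cisseae,Cissus,Cissus smithiana,B40
Cisseae,Cissus,Cissus sterculiifolia,B31
Cisseae,Cissus,Cissus subtetragona,B40
Cisseae,Cissus,Cissus trianae,B31
Cisseae,Cissus,Cissus tuberosa,B42
Cisseae,Cissus,Cissus verticillata,B31;B41;B42;B45
Cisseae,Cissus,Cissus willardii,B42
Cayratieae,Causonis,Causonis sp.,B46
Cayratieae,Cayratia,Cayratia cheniana,B46
Cayratieae,Cayratia,Cayratia geniculata,B31
Cayratieae,Cayratia,Cayratia imerinensis,B47
Cayratieae,Cayratia,Cayratia japonica,B31;B48
Cayratieae,Cayratia,Cayratia oligocarpa,B31
Cayratieae,Cayratia,Cayratia saponaria,B31
Cayratieae,Cayratia,Cayratia sp. [African],B46
Cayratieae,Cyphostemma,Cyphostemma elephantopus,B49
Cayratieae,Cyphostemma,Cyphostemma laza,B31
Cayratieae,Cyphostemma,Cyphostemma junceum,B31
Cayratieae,Pseudocayratia,Pseudocayratia dichromocarpa,B50
Cayratieae,Pseudocayratia,Pseudocayratia pengiana,B50
Cayratieae,Pseudocayratia,Pseudocayratia speciosa,B50;B51
Cayratieae,Tetrastigma,Tetrastigma campylocarpum,B52
Cayratieae,Tetrastigma,Tetrastigma cauliflorum,B52
Cayratieae,Tetrastigma,Tetrastigma caudatum,B52
Cayratieae,Tetrastigma,Tetrastigma delavayi,B52
Cayratieae,Tetrastigma,Tetrastigma dichotomum,B51
Cayratieae,Tetrastigma,Tetrastigma formosanum,B52
Cayratieae,Tetrastigma,Tetrastigma harmandi,B31
Cayratieae,Tetrastigma,Tetrastigma hemsleyanum,B31;B52
Cayratieae,Tetrastigma,Tetrastigma henryi,B52
Cayratieae,Tetrastigma,Tetrastigma hypoglaucum,B52
Cayratieae,Tetrastigma,Tetrastigma jinghongense,B52
Cayratieae,Tetrastigma,Tetrastigma kwangsiense,B30;B31
Cayratieae,Tetrastigma,Tetrastigma lanceolarium,B30
Cayratieae,Tetrastigma,Tetrastigma laoticum,B52
Cayratieae,Tetrastigma,Tetrastigma obovatum,B51;B52
Cayratieae,Tetrastigma,Tetrastigma obtectum,B51;B52
Cayratieae,Tetrastigma,Tetrastigma pachyllylum,B52
Cayratieae,Tetrastigma,Tetrastigma pedunculare,B31;B51;B52
Cayratieae,Tetrastigma,Tetrastigma petraeum,B52
Cayratieae,Tetrastigma,Tetrastigma retinervum,B52
Cayratieae,Tetrastigma,Tetrastigma rumicispermum,B31;B51;B52
Cayratieae,Tetrastigma,Tetrastigma serrulatum,B52
Cayratieae,Tetrastigma,Tetrastigma sichouense,B52
Cayratieae,Tetrastigma,Tetrastigma thorsborneorum,B52
Cayratieae,Tetrastigma,Tetrastigma triphyllum,B31;B52
Cayratieae,Tetrastigma,Tetrastigma xishuangbannaense,B31;B52
Parthenocisseae,Parthenocissus,Parthenocissus dalzielii,B36
Parthenocisseae,Parthenocissus,Parthenocissus heptaphylla,B31
Parthenocisseae,Parthenocissus,Parthenocissus henryana,B36
Parthenocisseae,Parthenocissus,Parthenocissus heterophylla,B36
Parthenocisseae,Parthenocissus,Parthenocissus himalayana,B53
Parthenocisseae,Parthenocissus,Parthenocissus laetevirens,B36
Parthenocisseae,Parthenocissus,Parthenocissus quinquefolia,B54
Parthenocisseae,Parthenocissus,Parthenocissus tricuspidata,B36;B37;B45
Parthenocisseae,Parthenocissus,Parthenocissus vitacea,B31
Parthenocisseae,Yua,Yua austro-orientalis,B31
Parthenocisseae,Yua,Yua chinensis,B31
Viteae,Ampelocissus,Ampelocissus acapulcensis,B30
Viteae,Ampelocissus,Ampelocissus bombycina,B30
Viteae,Ampelocissus,Ampelocissus bravoi,B42
Viteae,Ampelocissus,Ampelocissus cavicaulis,B30
Viteae,Ampelocissus,Ampelocissus erdvendbergiana,B30
Viteae,Ampelocissus,Ampelocissus grantii,B30
Viteae,Ampelocissus,Ampelocissus javalensis,B30;B42
Viteae,Ampelocissus,Ampelocissus latifolia,B30
Viteae,Ampelocissus,Ampelocissus macrocirrha,B30
Viteae,Ampelocissus,Ampelocissus martinii,B42
Viteae,Ampelocissus,Ampelocissus obtusata,B30
Viteae,Ampelocissus,Ampelocissus ochracea,B30
Viteae,Ampelocissus,Ampelocissus robinsonii,B30
Viteae,Vitis,Vitis aestivalis,B55
Viteae,Vitis,Vitis amurensis,B45;B56
Viteae,Vitis,Vitis brandoniana,B54
Viteae,Vitis,Vitis cinerea,B57
Viteae,Vitis,Vitis eolabrusca,B54
Viteae,Vitis,Vitis flexuosa,B54
Viteae,Vitis,Vitis grayensis,B58
Viteae,Vitis,Vitis labrusca,B45;B54;B59
Viteae,Vitis,Vitis lanatoides,B58
Viteae,Vitis,Vitis latisulcata,B58
Viteae,Vitis,Vitis palmata,B60
Viteae,Vitis,Vitis pseudorotundifolia,B54
Viteae,Vitis,Vitis rostrata,B54
Viteae,Vitis,Vitis rotundifolia,B31;B41;B54
Viteae,Vitis,Vitis rupestris,B45
Viteae,Vitis,Vitis tiliifolia,B61
Viteae,Vitis,Vitis tsoi,B31;B41
Viteae,Vitis,Vitis vulpina,B59;B62
Viteae,Vitis,Vitis wilsoniae,B31;B41
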