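species	family	mitochondrion
Balaena mysticetus	Balaenidae	NC_005268
Balaenoptera acutorostrata	Balaenopteridae	NC_005271
Balaenoptera bonaerensis	Balaenopteridae	NC_006926
Balaenoptera musculus	Balaenopteridae	MF409242
Delphinapterus leucas	Monodontidae	NC_034236
Eschrichtius robustus	Eschrichtiidae	NC_005270
Eubalaena japonica	Balaenidae	NC_006931
Globicephala melas	Delphinidae	NC_019441
Inia geoffrensis	Iniidae	NC_005276
Kogia breviceps	Kogiidae	NC_005272
Lagenorhynchus obliquidens	Delphinidae	NC_035426
Lipotes vexillifer	Lipotidae	NC_007629
Megaptera novaengliae	Balaenopteridae	NC_006927
Mesoplodon bidens	Ziphiidae	NC_042218
Monodon monoceros	Monodontidae	NC_005279
Neophocaena asiaeorientalis	Phocoenidae	NC_026456
Orcinus orca	Delphinidae	NC_023889
Phocoena phocoena	Phocoenidae	NC_005280
Phocoena sinus	Phocoenidae	MZ772969
Physeter catodon	Physeteridae	KU891394
Platanista minor	Platanistidae	NC_005275
Pontoporia blainvillei	Pontoporiidae	NC_005277
Sousa chinensis	Delphinidae	NC_012057
Tursiops aduncus	Delphinidae	KF570360
Tursiops truncatus	Delphinidae	EU557093
Ziphius cavirostris	Ziphiidae	KC776698
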