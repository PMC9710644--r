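#gene_family	level3	level2	level1
K00031	map00020	Energy_metabolism	Metabolism
K00036	map00030	Carbohydrate_metabolism	Metabolism
K00134	map00010	Carbohydrate_metabolism	Metabolism
K00627	map00010	Carbohydrate_metabolism	Metabolism
K00627	map00020	Energy_metabolism	Metabolism
K00627	map00620	Carbohydrate_metabolism	Metabolism
K00627	map00620	Energy_metabolism	Metabolism
K00688	map00500	Carbohydrate_metabolism	Metabolism
K00844	map00010	Carbohydrate_metabolism	Metabolism
K01647	map00020	Energy_metabolism	Metabolism
K01783	map00030	Carbohydrate_metabolism	Metabolism
K01810	map00010	Carbohydrate_metabolism	Metabolism
K01810	map00500	Carbohydrate_metabolism	Metabolism
K02863	map03010	Translation	Genetic_information_processing
K02886	map03010	Translation	Genetic_information_processing
K02906	map03010	Translation	Genetic_information_processing
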