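# SYNTHETIC stand-in for biome-specific decomposition kinetics.
# The measured cross-latitudinal Arrhenius parameters this table emulates are
# not redistributable here; these rows keep the documented qualitative
# gradient (higher temperature sensitivity of enzyme kinetics toward colder
# biomes) around the default decomposition parameters (v0D = 1e8, EvD = 47,
# K0D = 1.3e8, EKD = 30). Do not use for quantitative inference.
# biome 1 tropical forest, 2 temperate grassland, 3 temperate deciduous
# forest, 4 cold coniferous forest, 5 boreal forest/tundra.
biome,v0D,EvD,K0D,EKD
1,2.0e7,43,6.0e7,26
2,5.0e7,45,9.0e7,28
3,1.0e8,47,1.3e8,30
4,2.2e8,49,1.9e8,32
5,5.0e8,51,2.8e8,34
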