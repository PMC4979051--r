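g00001_p01	g00001
g00001_p02	g00001
g00001_p03	g00001
g00002_p01	g00002
g00002_p02	g00002
g00002_p03	g00002
g00003_p01	g00003
g00003_p02	g00003
g00003_p03	g00003
g00004_p01	g00004
g00004_p02	g00004
g00004_p03	g00004
g00005_p01	g00005
g00005_p02	g00005
g00005_p03	g00005
g00006_p01	g00006
g00006_p02	g00006
g00006_p03	g00006
g00007_p01	g00007
g00007_p02	g00007
g00007_p03	g00007
g00008_p01	g00008
g00008_p02	g00008
g00008_p03	g00008
g00009_p01	g00009
g00009_p02	g00009
g00009_p03	g00009
g00010_p01	g00010
g00010_p02	g00010
g00010_p03	g00010
g00011_p01	g00011
g00011_p02	g00011
g00011_p03	g00011
g00012_p01	g00012
g00012_p02	g00012
g00012_p03	g00012
g00013_p01	g00013
g00013_p02	g00013
g00013_p03	g00013
g00014_p01	g00014
g00014_p02	g00014
g00014_p03	g00014
g00015_p01	g00015
g00015_p02	g00015
g00015_p03	g00015
g00016_p01	g00016
g00016_p02	g00016
g00016_p03	g00016
g00017_p01	g00017
g00017_p02	g00017
g00017_p03	g00017
g00018_p01	g00018
g00018_p02	g00018
g00018_p03	g00018
g00019_p01	g00019
g00019_p02	g00019
g00019_p03	g00019
g00020_p01	g00020
g00020_p02	g00020
g00020_p03	g00020
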