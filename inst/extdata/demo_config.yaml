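# Demo configuration: the default study conditions, reduced replication
# kept at n = 3 as in the experiments the generator emulates.
noiseCV: 0.02
nReplicates: 3
artifactR: 0.20
naturalAbundance: 0.003663
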