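>insert117 synthetic spacer insert used to widen RIP1238-OBS spacing
ATAGCCTGCCCATAGGATATAGAGATACCAATAGTTGTTTGTGAACAGCAAAGAAGGATC
CAGAAGATCAGTCGCACGATATTGATGTGAATACTAGGTTTATAGGATAGTCGTACA
>insert100 synthetic spacer insert used to widen RIP317-OBS spacing
CCCATAGGATATAGAGATACCAATAGTTGTTTGTGAGCAACAAAGAAGGATCCAGAAGGT
CGATCGCACGATATTGATGTGAATACTAGTTGTAGTAATG
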