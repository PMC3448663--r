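>FRH_REF synthetic FrhB-core anchor reference [synthetic]
RLRKHFKVMWHTRHLTVGIKMSNYGWESIDGQNPVNSWDEFKTFRIRFFGMNPEVIDFYM
ITSLNKNGMLITNFMAIIKMDPWQVQADNLPYQGAIEDRNMFKSEGGKKHKGELGRTQIT
YIGSADVEHLTEYLQEGSAPHVFSHVDQWENAHADDDWLYHGPWTRVKTRSTENPYFERD
WPNVSIELMVTTEQRESESV
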