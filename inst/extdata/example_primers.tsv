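# pair_id	fwd_name	fwd_seq	rev_name	rev_seq
Bact0343_0908	S-D-Bact-0343-a-S-15	TACGGRAGGCAGCAG	S-D-Bact-0908-a-A-18	CCGTCAATTCMTTTRAGT
Bact0341_0785	S-D-Bact-0341-b-S-17	CCTACGGGNGGCWGCAG	S-D-Bact-0785-a-A-21	GACTACHVGGGTATCTAATCC
Univ27F_1492R	27F	AGAGTTTGATCMTGGCTCAG	1492R	TACGGYTACCTTGTTACGACTT
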