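>BT0356_oligo 65-bp araM promoter fragment with two tandem AraR boxes
cccccATATAAGAGTGTATTTGATACACCAAACAAAAGTGTTACTTTTACACCCAAAATAccccc
>BT0365_oligo 41-bp promoter fragment with a single AraR box
cccccTACTCAAAGTGTAAAAAAGACACTTATATAAccccc
>shuffled_control 65-bp mononucleotide-shuffled BT0356 fragment (negative control)
cccccACTATAATTAACCAATTAATCTAATCCAACGGTTACATAGGAGGTACTAATATA Accccc
>crystallization_duplex 27-bp duplex spanning the 22-nt araM operator core
GCAAAAGTGTTACTTTTACACCCATGC
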