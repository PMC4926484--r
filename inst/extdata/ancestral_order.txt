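>insect_ancestral
CR,I,-Q,M,ND2,W,-C,-Y,COI,L2,COII,K,D,ATP8,ATP6,COIII,G,ND3,A,R,N,S1,E,-F,-ND5,-H,-ND4,-ND4L,T,-P,ND6,CytB,S2,-ND1,-L1,-lrRNA,-V,-srRNA
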