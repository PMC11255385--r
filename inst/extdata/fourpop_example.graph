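# Four populations, one migration edge from the branch ancestral to pop2
# into the pop3 tip. Lengths in drift units; MIG edges carry no length.
ROOT R
BRANCH R A 0.02
BRANCH A P1 0.04
BRANCH A s 0.015
BRANCH s P2 0.025
BRANCH R B 0.02
BRANCH B P3 0.03
BRANCH B P4 0.04
MIG m1 s P3
LEAF P1 pop1
LEAF P2 pop2
LEAF P3 pop3
LEAF P4 pop4
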