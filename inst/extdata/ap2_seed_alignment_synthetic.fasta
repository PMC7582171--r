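>ap2_seed_1 synthetic hand-built AP2/ERF-domain-like seed sequence
SKYRGVRQRPWGKWVAEIRDPRKAARVWLGTFDTAEEAARAYDRAALDFRGPRAKLNFPE
>ap2_seed_2 synthetic hand-built AP2/ERF-domain-like seed sequence
SKFRGVRQRPWGKWVAEIRDPKKAARVWLGTFDTAEEAARAYDKAALDFRGPRAKLNFPE
>ap2_seed_3 synthetic hand-built AP2/ERF-domain-like seed sequence
SKYRGVRRRPWGKWVAEIRDPRKAARVWLGTYDTAEEAARAYDRAALDFRGPRAKLNFSE
>ap2_seed_4 synthetic hand-built AP2/ERF-domain-like seed sequence
SKYRGVRQRPWGKFVAEIRDPRKAARVWLGTFDTAEEAARAYDRAAIDFRGPRAKLNFPE
>ap2_seed_5 synthetic hand-built AP2/ERF-domain-like seed sequence
TKYRGVRQRPWGKWVAEIRDPRKAARVWLGTFDTAEDAARAYDRAALDFRGPRAKLNFPE
>ap2_seed_6 synthetic hand-built AP2/ERF-domain-like seed sequence
SKYRGVRQRPWGKWVAEIRNPRKAARVWLGTFDTAEEAARAYDRAALDFRGARAKLNFPE
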