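>b3_seed_1 synthetic hand-built B3-domain-like seed sequence
RLFGVNLTESAGKKWEVRLVYRDGRVWFSDGWKEFVKANG
>b3_seed_2 synthetic hand-built B3-domain-like seed sequence
RLFGVNLTESAGKKWEVRLVYRDGRAWFSDGWKEFVRANG
>b3_seed_3 synthetic hand-built B3-domain-like seed sequence
RLFGVNLSESAGKKWEVRLVYRDGRVWFSDGWKEFVKANG
>b3_seed_4 synthetic hand-built B3-domain-like seed sequence
RLFGVNLTESAGRKWEVRLVYRDGRVWFSEGWKEFVKANG
>b3_seed_5 synthetic hand-built B3-domain-like seed sequence
KLFGVNLTESAGKKWEVRLVYRDGRVWFSDGWKEFVKANG
>b3_seed_6 synthetic hand-built B3-domain-like seed sequence
RLFGVNLTESAGKKWEVKLVYRDGRVWFSDGWREFVKANG
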