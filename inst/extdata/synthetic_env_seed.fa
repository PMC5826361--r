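>SYN_ENV_SEED synthetic 540-residue envelope-like seed protein (not a real viral sequence)
ELFGRSPIEAWTIRQRELVIDACGNNYQLRPRQKKRGTPQLPRAQAFFMFACSTSRQSNP
ASPHKFTTNGNFNDARCMDRHFNGTTKAIRLMGKHFKEGYPLMDARFPDLTLMKMLEQPE
ADPHWMTSKECSSKMRRRWLLIVCSDQLPPPSKFQKECNQLFNLLSHSAEKCEVQGCFLY
YTEHNLLPSVKKVGRLDTYLNIFLHSMTLIEYALLPLPLGSPKLNSKNNNPGQLKEEVAA
LQVSPPNPTRQDGRRPQLFGRAGSLHTYLVEEVHDIPAPLFAFCGEIDFITGSAKIKCFI
TAGNTLTRCSAPTPPRQHTLPRNDPTAACLPTLMIIELIDEASNIPGERASWVKGRHSYG
WPGCFNITLETGYQPRGDDGLKHTSGVPILQVVICRLPFIVHPISLLQAGVGNTASCAQK
GVQASASKEQCLLGYYGGLFNLQILVDPLYEYTLAIFNVANTDPMLRGFSNEEARSSIGF
ATLSPRAEPVVLGQLTLPEDYVLQNVPYVLVISAYDSLRSIEKDVFLENNEFCTVLSSSL
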