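>toy_a synthetic background record
MKTAYIAKQRQGLMNDVFGHEPWKRACDEFGHIKLMNPQRSTVWYAC
>toy_b carries a planted ISSTN serine-stretch instance
MGDKPLVHAQISSTNWERTYLPAGCDEFHIKMNQRSVWYAGDKPLVH
>toy_c synthetic background record
MSAHLKGWERTYPQNDCVFMIKLAGHESTWRACDEFGHIKLMNPQRS
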