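>TBA1A_SYNFRAG synthetic tubulin alpha-1A fragment embedding worked-example peptides
MSVRAFVHWYVGEGMEEGEFSEARKTIGGGDDSFNTFFSETGA
>MAP2_SYNFRAG synthetic MAP2 fragment embedding the STKSPR cross-link partner
MGERSTKSPRDSLSQQLNSKEADSLSR
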