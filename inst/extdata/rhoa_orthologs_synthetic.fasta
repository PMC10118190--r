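>orthologA_synthetic demo GTPase, species A
VETLNLEEWASKFIYMQKCNWLFTCSNFIKDGSMCKHEFDLQVTCLPNKKSVTNKWFCMLHVYGYMDFCCKTKAYYPEQITCHRQRTSNFNWHGWLWVWMEAAMGVRISHMVMLTSWKMGRNCCFDGQLLTFSSNGPECSQGRIWTSGSTWGVRRIGSMNYMWTTSRPKRVVKFIWNYMQCDYQEELCLR
>orthologB_synthetic demo GTPase, species B (~94% identical)
VETLNHEELASKFIYMQKCNILFTGSNFIKDGSMCKHEFDLCVTCLPRKKSCTNKWFCMLHVYGYCDFCCKTKAYYPEQITCHRQRTSNFNWHGWLWVWMEAAMGVRISHMVMLTSWKTGRNCCFDAQHLTFSSNHPECSQGRIWTSGSTWGVRRIGSMNYMWTTSRPKRVVKFIWNYMQCDYQEELCLR
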