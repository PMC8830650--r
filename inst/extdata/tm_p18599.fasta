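>sp|P18599|5HT2A_CRIGR 5-hydroxytryptamine receptor 2A, residues 1-100
MEILCEDNTSLSSIPNSLMQVDGDSGLYRNDFNSRDANSSDASNWTIDGENRTNLSFEGY
LPPTCLSILHLQEKNWSALLTAVVIILTIAGNILVIMAVS
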