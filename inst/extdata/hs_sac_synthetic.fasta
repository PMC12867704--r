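>HsSAC_t_synthetic species=Homo_sapiens group=mammal synthetic stand-in, human sAC numbering
AQLVIKGENPMRSTIIILFADVVAFEAQVNDPPRMQTTQTTSKTGADSTQVSCFQYPGKA
VIAMDQPISNDRDVIVFFNMEGLIKESIRLYTVLKQAGDPEASLLNPSEASPGCMMLDLT
NEGSLLTDTSRRFGLGDAVQTVKKVEYETKTVADDKSRPLDKNFAGTTISTIHKDRTRGL
SIELGECSDNAEESAPLTSVSFVAKPTPPLVKPNGNPKLRGSWVSQKSDSKWYFSTKLGQ
TFATTHAWRVKFGVVISYAAYFVLVNAVNVFTEGREAGPKHSYVMSTISIVQGSGAAYAE
KFTGVLTAVSPIKHENGNRSNSIQLSVTVRTGGKFEAFDKGNEGVVEERRTATLVKMDGG
PELVGFSVRAVGLARNALCRVSLGHRSKSGVPKLNKYGPQTPDFPLRQLCLNAKARIGFD
CYLSESRLFWISVLVVHRPFTRARPPTNGAEPEHAIEGMYVLTAVIDISK
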