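plant_id	printed_label
BP06	hydrogenotrophic
BP07	hydrogenotrophic
BP08	hydrogenotrophic
BP12	hydrogenotrophic
BP15	both
BP10	hydrogenotrophic
BP13	hydrogenotrophic
BP01	acetoclastic
BP16	hydrogenotrophic
BP05	acetoclastic
BP02	acetoclastic
BP03	acetoclastic
BP04	hydrogenotrophic
BP14	acetoclastic
BP09	both
BP11	both
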