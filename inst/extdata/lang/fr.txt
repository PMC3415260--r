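Le train du matin a quitté la gare avec quelques minutes de retard, et les
voyageurs regardaient les champs défiler derrière les fenêtres pendant que
la lumière changeait lentement. On dit souvent que la meilleure façon de
connaître une ville est de parcourir ses rues tôt le matin, quand les
boutiques sont encore fermées et que les boulangers sont les seuls au
travail. Il fut un temps où chaque village avait son propre marché, et les
gens venaient des fermes voisines avec ce qu'ils avaient cultivé ou
fabriqué pendant la semaine. Le temps peut changer très vite dans cette
région, et l'on conseille aux voyageurs d'emporter un manteau même pendant
les mois d'été. Elle écrivait des lettres à ses amies chaque dimanche soir,
racontant les petites choses de la semaine et demandant des nouvelles de
leurs familles. La bibliothèque au coin de la rue est ouverte depuis plus
de cent ans, et la salle de lecture sent encore le vieux papier et le bois
ciré. Quand le pont fut enfin terminé, les deux moitiés de la ville se sont
rejointes, et une génération plus tard personne ne se souvenait de la vie
d'avant. La plupart des gens pensent qu'un bon repas partagé entre amis
reste un des plaisirs les plus simples de la vie quotidienne.
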